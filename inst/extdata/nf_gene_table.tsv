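gene	species	gene_id	rank
DMI1	Mt	Medtr2g005620	1
DMI1	Ca	Ca_00033	1
DMI1	Lj	Lj6.CM0508.260.r2.m	1
DMI1	Cc	C.cajan_17266	1
DMI1	Cc	C.cajan_11017	2
DMI1	Pv	Phvulv091019046m	1
DMI1	Gm	Glyma12g28860	1
DMI1	Gm	Glyma16g00500	2
DMI1	Gm	Glyma19g45310	3
DMI2	Mt	Medtr5g032400	1
DMI2	Ca	Ca_11537	1
DMI2	Ca	Ca_17066	2
DMI2	Lj	Lj2.CM0177.340.r2.m	1
DMI2	Cc	C.cajan_12295	1
DMI2	Pv	Phvulv091027352m	1
DMI2	Gm	Glyma09g33510	1
DMI2	Gm	Glyma01g02460	2
DMI3	Mt	Medtr8g047760	1
DMI3	Mt	Medtr5g009940	2
DMI3	Ca	Ca_15707	1
DMI3	Lj	Lj3.LjT02O17.60.r2.m	1
DMI3	Cc	C.cajan_46131	1
DMI3	Pv	Phvulv091013422m	1
DMI3	Gm	Glyma15g35070	1
DMI3	Gm	Glyma08g24360	2
DMI3	Gm	Glyma10g11020	3
ERN1	Mt	Medtr7g102550	1
ERN1	Mt	Medtr6g031080	2
ERN1	Ca	Ca_08232	1
ERN1	Lj	Lj1.CM0104.2670.r2.m	1
ERN1	Cc	C.cajan_08385	1
ERN1	Cc	C.cajan_16144	2
ERN1	Pv	Phvulv091004951m	1
ERN1	Gm	Glyma16g04410	1
ERN1	Gm	Glyma19g29000	2
ERN3	Mt	Medtr6g015110	1
ERN3	Mt	Medtr4g134350	2
ERN3	Ca	Ca_08582	1
ERN3	Lj	Lj4.CM0046.750.r2.a	1
ERN3	Cc	C.cajan_23330	1
ERN3	Pv	Phvulv091030938m	1
ERN3	Gm	Glyma08g12130	1
ERN3	Gm	Glyma05g29011	2
FLOT2	Mt	Medtr3g137870	1
FLOT2	Mt	Medtr1g099720	2
FLOT2	Cc	C.cajan_09162	1
FLOT2	Pv	Phvulv091009868m	1
FLOT2	Gm	Glyma06g06930	1
FLOT2	Gm	Glyma04g06830	2
IPD3	Mt	Medtr5g027010	1
IPD3	Ca	Ca_10616	1
IPD3	Lj	Lj2.CM0803.150.r2.m	1
IPD3	Cc	C.cajan_12408	1
IPD3	Pv	Phvulv091016359m	1
IPD3	Gm	Glyma01g35255	1
IPD3	Gm	Glyma09g34695	2
LIN	Mt	Medtr1g112060	1
LIN	Ca	Ca_08341	1
LIN	Lj	Lj5.CM0909.400.r2.m	1
LIN	Cc	C.cajan_22455	1
LIN	Pv	Phvulv091027173m	1
LIN	Gm	Glyma10g33851	1
LIN	Gm	Glyma12g29771	2
LYK3	Mt	Medtr5g093450	1
LYK3	Mt	Medtr5g093440	2
LYK3	Mt	Medtr5g093730	3
LYK3	Mt	Medtr5g093410	4
LYK3	Ca	Ca_10278	1
LYK3	Lj	Lj2.CM0545.250.r2.m	1
LYK3	Lj	Lj6.CM0041.460.r2.a	2
LYK3	Cc	C.cajan_09999	1
LYK3	Cc	C.cajan_15801	2
LYK3	Pv	Phvulv091021871m	1
LYK3	Gm	Glyma14g05060	1
LYK3	Gm	Glyma02g43860	2
LYK3	Gm	Glyma02g43850	3
LYR3	Mt	Medtr5g019000	1
LYR3	Ca	Ca_02085	1
LYR3	Lj	Lj2.CM0323.420.r2.d	1
LYR3	Cc	C.cajan_12623	1
LYR3	Pv	Phvulv091008254m	1
LYR3	Gm	Glyma11g06750	1
LYR3	Gm	Glyma01g38550	2
LYR3	Gm	Glyma02g06700	3
NFP	Mt	Medtr5g018990	1
NFP	Mt	Medtr8g093910	2
NFP	Ca	Ca_02086	1
NFP	Ca	Ca_16029	2
NFP	Lj	Lj2.CM0323.400.r2.d	1
NFP	Cc	C.cajan_12621	1
NFP	Pv	Phvulv091008306m	1
NFP	Gm	Glyma11g06740	1
NFP	Gm	Glyma01g38560	2
NIN	Mt	Medtr5g106690	1
NIN	Ca	Ca_09832	1
NIN	Lj	Lj2.CM0102.250.r2.m	1
NIN	Cc	C.cajan_33924	1
NIN	Cc	C.cajan_37712	2
NIN	Pv	Phvulv091031090m	1
NIN	Pv	Phvulv091004689m	2
NIN	Gm	Glyma06g00240	1
NIN	Gm	Glyma04g00210	2
NIN	Gm	Glyma02g48080	3
NRT1	Mt	Medtr5g093170	1
NRT1	Ca	Ca_10291	1
NRT1	Lj	Lj2.CM0826.350.r2.m	1
NRT1	Lj	Lj2.CM0826.370.r2.m	2
NRT1	Lj	Lj2.CM0545.330.r2.m	3
NRT1	Cc	C.cajan_09986	1
NRT1	Pv	Phvulv091021785m	1
NRT1	Gm	Glyma02g43740	1
NRT1	Gm	Glyma14g05170	2
NSP1	Mt	Medtr8g025000	1
NSP1	Mt	Medtr5g015580	2
NSP1	Mt	Medtr8g101580	3
NSP1	Ca	Ca_10004	1
NSP1	Lj	Lj3.CM0416.1260.r2.d	1
NSP1	Cc	C.cajan_27701	1
NSP1	Pv	Phvulv091018505m	1
NSP1	Pv	Phvulv091030806m	2
NSP1	Pv	Phvulv091007340m	3
NSP1	Gm	Glyma07g04430	1
NSP1	Gm	Glyma16g01020	2
NSP1	Gm	Glyma05g22460	3
NSP2	Mt	Medtr3g097800	1
NSP2	Mt	Medtr5g065380	2
NSP2	Ca	Ca_26279	1
NSP2	Ca	Ca_23494	2
NSP2	Lj	Lj1.CM1976.90.r2.m	1
NSP2	Cc	C.cajan_01355	1
NSP2	Cc	C.cajan_32376	2
NSP2	Pv	Phvulv091012665m	1
NSP2	Gm	Glyma04g43090	1
NSP2	Gm	Glyma06g11610	2
NSP2	Gm	Glyma13g02840	3
RRP1	Mt	Medtr1g074280	1
RRP1	Ca	Ca_26056	1
RRP1	Ca	Ca_19055	2
RRP1	Lj	Lj5.CM1077.650.r2.m	1
RRP1	Cc	C.cajan_33337	1
RRP1	Pv	Phvulv091005582m	1
RRP1	Gm	Glyma13g21080	1
RRP1	Gm	Glyma10g07190	2
SKL1	Mt	Medtr7g121800	1
SKL1	Ca	Ca_12043	1
SKL1	Lj	Lj1.CM0012.1100.r2.m	1
SKL1	Cc	C.cajan_45110	1
SKL1	Pv	Phvulv091008769m	1
SKL1	Gm	Glyma03g33850	1
SKL1	Gm	Glyma13g20810	2
SKL1	Gm	Glyma10g06610	3
SUNN	Mt	Medtr4g096420	1
SUNN	Mt	Medtr4g096400	2
SUNN	Ca	Ca_15399	1
SUNN	Ca	Ca_09375	2
SUNN	Lj	Lj3.CM0091.1690.r2.m	1
SUNN	Cc	C.cajan_21258	1
SUNN	Cc	C.cajan_24880	2
SUNN	Cc	C.cajan_39327	3
SUNN	Pv	Phvulv091015304m	1
SUNN	Gm	Glyma12g04390	1
SUNN	Gm	Glyma11g12186	2
N56	Mt	Medtr1g146810	1
N56	Ca	Ca_13985	1
N56	Ca	Ca_26114	2
N56	Lj	Lj5.CM0492.390.r2.m	1
N56	Lj	Lj1.CM0001.650.r2.m	2
N56	Lj	Lj1.CM0001.690.r2.m	3
N56	Lj	Lj1.CM0001.710.r2.m	4
N56	Cc	C.cajan_07899	1
N56	Cc	C.cajan_37827	2
N56	Cc	C.cajan_46126	3
N56	Pv	Phvulv091005854m	1
N56	Gm	Glyma10g44180	1
N56	Gm	Glyma20g38950	2
N56	Gm	Glyma13g12484	3
N56	Gm	Glyma19g29920	4
N56	Gm	Glyma19g29880	5
ENOD93	Mt	Medtr8g119590	1
ENOD93	Ca	Ca_06646	1
ENOD93	Cc	C.cajan_46055	1
ENOD93	Cc	C.cajan_26197	2
ENOD93	Cc	C.cajan_26199	3
ENOD93	Pv	Phvulv091017136m	1
ENOD93	Gm	Glyma06g24760	1
ENOD93	Gm	Glyma05g08400	2
ENOD93	Gm	Glyma17g12600	3
ENOD93	Gm	Glyma17g12610	4
ENOD93	Gm	Glyma05g08380	5
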