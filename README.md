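# KsScape

Comparative molecular evolution for small curated gene families across
related genomes — built around the nitrogen-fixation (NF) gene
complement of six legumes (*Medicago truncatula* Mt, *Cicer arietinum*
Ca, *Lotus japonicus* Lj, *Cajanus cajan* Cc, *Phaseolus vulgaris* Pv,
*Glycine max* Gm).

Given per-species CDS collections (or the bundled simulator's output),
the package runs the full desk-scale analysis a comparative genomicist
would otherwise stitch together from BLAST, Clustal, orthoMCL and MEGA:

1. **Homology** — seed-and-extend Smith–Waterman search with
   Karlin–Altschul E-values (E = K·m·n·e^(−λS)), the ≥ 70% identity /
   E ≤ 1e−50 filter, bidirectional best hits, connected-component gene
   families, and the ≥ 4-of-6-species selection rule.
2. **Codon-aware alignment** — progressive alignment in amino-acid
   space (BLOSUM62) with back-translation, and complete deletion of
   gapped/ambiguous codon columns.
3. **Rates** — Nei–Gojobori (1986) counting with stop-excluded site
   fractions and pathway-averaged differences, Jukes–Cantor correction
   (Ks = −(3/4)·ln(1 − (4/3)·ps), Ka analogously), saturation flags,
   and Ka/Ks per pair.
4. **Trees** — deterministic neighbor-joining with codon-column
   bootstrap supports, and the one- vs two-cluster reading that
   separates orthologs from outparalogs.
5. **Classification** — ortholog / inparalog / outparalog labels from
   species + cluster evidence (Ks threshold 0.40 as the one-cluster
   fallback), tandem flags from gene-order adjacency.
6. **Ks landscape** — proportional Ks histograms per species pair, peak
   detection, and dating windows (≤ 0.15 recent WGD; 0.15–0.50
   speciation; 0.50–0.80 ancient duplication), plus species-pair Ks
   medians, closest/farthest species reports and per-gene selection
   summaries.

A codon sequence-evolution simulator with known duplication histories
(ancient pre-speciation duplication, lineage-confined WGD, tandem
duplication, gene loss) generates six-species datasets whose truth
labels score every downstream stage. The species-tree calibration
reproduces the published ortholog Ks medians of the six legumes, so
simulated landscapes resemble the real ones: a Gm–Gm peak at Ks ≈ 0.1
(the soybean WGD), speciation peaks near Ks 0.4 (Mt–Ca lower, between
0.2 and 0.3), and ancient-duplication peaks at Ks 0.6–0.7.

## Worked example

```r
library(KsScape)

cfg <- defaultPipelineConfig(seed = 1, n_families = 20, bootstrap = 200)
res <- runPipeline(cfg, out_dir = "ksscape_out")
#> [simulate] done in 3.8s (n_sequences=259)
#> [search] done in 83.5s (n_hits=12042, n_pass=3108, n_bbh=488)
#> [families] done in 0.1s (n_families=20)
#> [align] done in 5.7s (n_alignments=20)
#> [rates] done in 2.0s (n_pairs=1554)
#> [trees] done in 6.5s (n_trees=20, bootstrap=200)
#> [classify] done in 0.1s (n_pairs=1554, accuracy=1)
#> [landscape] done in 0.0s (n_distributions=21, n_peaks=37)

res$evaluation$accuracy
#> [1] 1                      # all 1554 pair relations recovered
res$evaluation$tandem_accuracy
#> [1] 1
subset(res$peaks, species_pair %in% c("Gm-Gm", "Gm-Mt"))
#>    species_pair center proportion                type
#> 21        Gm-Gm   0.05  0.1704545          recent_wgd
#> 22        Gm-Gm   0.55  0.3181818 ancient_duplication
#> 25        Gm-Mt   0.35  0.2634731          speciation
#> 26        Gm-Mt   0.65  0.2275449 ancient_duplication
res$selection$global_mean
#> [1] 0.2091409              # mean Ka/Ks at simulated omega = 0.2
```

Reading the output: the Gm–Gm self-distribution peaks in the first bins
(the recent WGD) and again near 0.55–0.6 (copies separated by the
ancient duplication), with nothing in the speciation window — the
signature that soybean's extra copies are duplicates, not hidden
orthologs. Cross-species distributions peak at the speciation Ks and
again in the ancient window where outparalogs accumulate. The
species-pair summary names the closest pair by counting, per gene
family, which pair attains the lowest ortholog Ks.

`runPipeline` writes every intermediate table (hits, BBH pairs,
families, rates, classification, Newick trees, distributions, peaks,
summaries) plus a JSON manifest with seed, thresholds and per-stage row
counts. The same analysis is scriptable from a shell via
`inst/scripts/kspipe.R` (`simulate` and `run` subcommands).

The bundled curated gene table is available as `nfGeneTable()`;
`countGenesOnChromosome(nfGeneTable(), "Mt", "5")` returns `7` — the
seven NF genes on Mt chromosome 5 (*DMI2, IPD3, LYK3, LYR3, NFP, NIN,
NRT1*), parsed from the `MedtrNg…` identifier convention.

## Using real genome data

The analysis was designed against the public CDS releases the NF study
used (Phytozome Mt v3.0, Pv v1.0, Gm v1.1; Ca v1.0; Lj v2.5; Cc v5.0).
Those releases are not bundled — fetching them requires network access
— but the pipeline accepts them directly: read per-species FASTA with
`readCdsFasta()`, attach gene positions from GFF3
(`gff3Positions()`) or a 4-column TSV, and pass the `CdsSet` to
`pipelineConfig(cds = ...)`. Precomputed BLAST tabular output can
replace the internal search via `readHits()`. With the Gm v1.1 CDS in
hand, the classic checks are
`ng86` on the aligned pair Glyma12g28860/Glyma16g00500 (Ks ≈ 0.04, an
inparalog pair from the recent WGD) and Glyma05g22460/Glyma07g04430
(Ks ≈ 0.685, outparalogs from the ancient duplication).

## Scope

Maximum-likelihood/parsimony trees, ML codon models, mixture-model Ks
decomposition, absolute-time dating, synteny-block detection and
genome downloading are deliberately out of scope. See the methods
vignette (`vignettes/ks-landscapes.Rmd`) for the models, parameter
defaults, design decisions and known limitations.
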