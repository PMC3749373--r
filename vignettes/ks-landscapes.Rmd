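---
title: "Dating gene-family duplications with Ks landscapes: models and design choices"
author: "KsScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating gene-family duplications with Ks landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KsScape)
```

## The problem

Legume genomes carry the traces of repeated polyploidy: an ancient
whole-genome duplication predating the radiation of the Papilionoideae,
a much younger duplication confined to soybean (*Glycine max*), and a
steady trickle of tandem duplications. For a curated set of gene
families — here modelled on the nitrogen-fixation gene complement of six
legumes (*Medicago truncatula* Mt, *Cicer arietinum* Ca, *Lotus
japonicus* Lj, *Cajanus cajan* Cc, *Phaseolus vulgaris* Pv, *Glycine
max* Gm) — one wants to know, for every pair of homologs, whether they
are orthologs (separated by speciation), inparalogs (duplicated after
the relevant speciation) or outparalogs (duplicated before it), whether
a pair arose by tandem duplication, and how the family's duplication
history maps onto the genome-wide events.

The dating currency is **Ks**, the number of synonymous substitutions
per synonymous site. Synonymous change is approximately neutral, so Ks
accumulates roughly clock-like: pairs born at the same event pile up at
the same Ks, and a histogram of pair-wise Ks values — a *Ks
proportional plot* — shows one peak per event. **Ka/Ks** (the
nonsynonymous analogue over Ks, also written ω) measures selection
pressure: values far below 1 indicate strong purifying selection, as
expected for genes whose function is essential.

## The estimation model

**Counting (NG86).** Sites are counted per codon position: the
synonymous fraction of a position is the number of its three
single-nucleotide alternatives that preserve the amino acid, divided by
the number of alternatives that are not stop codons; the nonsynonymous
fraction is the complement, so S + N is exactly three times the codon
count. Differences between two codons that differ at k positions are
averaged over all k! orderings of single steps, excluding any pathway
that passes through a stop codon; if every pathway is blocked, the
direct differences are counted as nonsynonymous. Both tables are
precomputed for all sense-codon pairs and verified in the test suite
against brute-force enumeration.

**Correction.** Observed proportions ps = Sd/S and pn = Nd/N are
corrected for multiple hits with the Jukes–Cantor transform
d = −(3/4)·ln(1 − (4/3)·p). When the log argument is non-positive the
rate is *saturated*: it is reported as undefined with a flag rather
than as infinity, and all downstream medians, histograms and means skip
undefined values. Ka/Ks is undefined when Ks = 0 or either rate is
saturated. The package also reports the plain p-distance and its
JC-corrected counterpart for every pair; the corrected value is the
default tree-building distance.

The choice of NG86-with-JC is deliberate: it is the standard equal-path
counting method, fully specifiable, and testable against hand
enumeration — properties that matter more here than the marginal
accuracy gains of maximum-likelihood codon models, which are out of
scope (the configuration reserves hooks for alternative estimators).

## Alignment

Ks estimation needs codon-respecting alignments. Pairs and families are
aligned in amino-acid space (BLOSUM62, affine gap penalties 10/0.5) and
back-translated, so every gap run is a whole number of codons and the
reading frame survives. Multiple alignments are progressive: a guide
tree from amino-acid k-mer distances (average linkage), then
profile–profile alignment leaf-to-root with sum-of-pairs BLOSUM scores
(a small C++ kernel). Before any rate is computed, *complete deletion*
removes every codon column in which any row has a gap or an ambiguous
base (IUPAC codes count as gaps); removal is by whole codons so site
counts stay codon-consistent. Pairwise deletion is intentionally not
offered — it would make site counts incomparable across pairs of the
same family.

## Homology search and family assembly

The search engine is a desk-scale stand-in for a BLASTN run: candidate
pairs must share an exact 11-mer word, survivors get a full
Smith–Waterman local alignment with BLASTN-like scoring (match +2,
mismatch −3, gap open 5, extend 2), and E-values follow the
Karlin–Altschul formula E = K·m·n·exp(−λ·score) with λ = 0.625,
K = 0.41, m the query length and n the summed CDS length of the
subject's species. At the few hundred sequences this package targets,
exact Smith–Waterman is affordable and removes heuristic variance; a
12-column tabular reader accepts hits from a real BLAST run as a
drop-in replacement. Hits are filtered at ≥ 70% identity and
E ≤ 1e−50 (both boundaries inclusive; only the E-value boundary is
conventionally written with ≤, and the identity boundary is documented
here as a choice). Orthology is confirmed by bidirectional best hits
(best = bit score, then E-value, then identity, then subject id, for
determinism), families are connected components of the filtered hit
graph seeded at anchor genes, and a family qualifies for analysis when
it spans at least four of the six species. Connected components stand
in for Markov clustering here: the families are anchored single genes
and clustering is confirmatory, not exploratory.

## Trees and the one- vs two-cluster call

Gene trees are neighbor-joining on the JC distance, implemented in the
package so that two numerical corners are pinned down: ties in the Q
criterion resolve to the smallest (i, j) index pair, and negative
branch-length estimates are clamped to zero. The implementation is
exact on additive matrices (a property test, and a cross-check against
an independent NJ implementation, enforce this). Bootstrap supports
resample *codon columns*, not single nucleotides, to respect the coding
structure; the default is 1000 replicates, and supports are attached as
internal node labels.

A family tree is read as *two clusters* — the signature of a
pre-speciation duplication — via a formalization of what is otherwise a
visual call: the candidate split is the longest internal edge (ties:
higher support, then lexicographically smallest tip set), accepted only
if its bootstrap support reaches 50 and **at least one species has
members on both sides of the split**. The species condition is the
biological content of the call: a cluster split that merely separates
taxonomic groups is a speciation signal, while outparalogy means the
same genome keeps copies on both sides. Without it, any family spanning
the deep Phaseoloid/Hologalegina split would be cut in two and its
orthologs mislabelled. When species information is absent the fallback
is the weaker requirement of two tips per side. The support threshold
is configurable; 50 is a default, not a claim.

## Classification

With a partition in hand the decision table is: same species + same
cluster → inparalog; same species + different clusters → outparalog;
different species + same cluster → ortholog; different species +
different clusters → outparalog. One-cluster families have no
outparalog evidence from the tree, so same-species pairs fall back to a
Ks threshold of 0.40 — between the speciation peak near 0.4 and the
observed outparalog averages near 0.5; a same-species pair with
undefined Ks defers to cluster evidence and stays an inparalog. Tandem
pairs are same-species pairs on the same chromosome whose gene-order
indices differ by at most 1 (configurable); synteny proper is out of
scope, and (chromosome, order index) adjacency is the deliberate
approximation.

## The landscape

Per species pair, defined Ks values (tandem-derived pairs excluded) are
binned at width 0.1 up to Ks 2.0 and normalised to proportions; values
beyond the limit go to an overflow count so the books always close.
Peaks are bins strictly above both flanking bins, with runs of tied
bins treated as one candidate resolved toward the lower-Ks bin, and a
minimum height of 0.10 so that genuinely small ancient peaks still
register without picking up noise. Peak typing follows the dating
windows: centre ≤ 0.15 → recent WGD; (0.15, 0.50] → speciation —
widened downward from a point at 0.4 because the youngest split in the
six-legume calibration (Mt–Ca) peaks between 0.2 and 0.3; (0.50, 0.80]
→ ancient duplication; beyond → unassigned. Bin width, height floor
and windows are all configuration, declared substitutes for choices the
visual analysis never had to make explicit. Mixture-model decomposition
of the Ks distribution and absolute-time dating are non-goals.

Species-pair summaries report the ortholog Ks median (tandem excluded),
the mean Ka/Ks, and for each gene family which species pair attains the
lowest (and highest) ortholog Ks; the closest pair maximises the
lowest-Ks count with the lower median as tie-break, the farthest
symmetrically. Selection is summarised per gene as the mean defined
Ka/Ks, categorised as strong negative (< 0.3, calibrated to the most
conserved families), negative (≤ 1) or positive (> 1) — the category
names carry no claim about the strength of positive selection.

## The simulator

The real analysis runs on six downloaded genome releases; this package
instead ships a generative stand-in so that every stage is testable by
recovery of known truth. The simulator is honest about being a choice:
no generative model exists for the real data, so all distributions here
are this package's defaults.

* **Species tree.** Six tips, Phaseoloid (Gm, Pv, Cc, as a polytomy)
  versus Hologalegina (Lj sister to Mt + Ca), with branch lengths in dS
  units solved so that the additive tip-to-tip distances reproduce all
  nine published ortholog Ks medians exactly (Gm–Cc and Gm–Pv 0.212,
  Gm–Lj 0.331, Gm–Ca 0.336, Gm–Mt 0.398, Mt–Ca 0.282, Mt–Pv 0.400,
  Mt–Cc 0.405, and Pv–Cc implied at 0.214). These are calibration
  defaults, not assertions about the species.
* **Sequence evolution.** A branch of length t applies round(t·S)
  synonymous and round(ω·t·N) nonsynonymous single-nucleotide
  substitutions (S, N the NG86 site counts of the branch's starting
  sequence) at uniformly chosen eligible positions, re-drawing whenever
  a stop codon would arise — the simplest process that preserves coding
  integrity. Substitution counts are rounded to integers; at the
  default 300 codons the discretization bias stays below 0.01 dS.
  There are no indels, no among-site rate variation and no codon-usage
  bias (all declared non-goals), which means gap handling and alignment
  robustness are exercised by constructed cases in the tests rather
  than by the simulator.
* **Events.** Ancient duplications sit on the root stem at an offset
  chosen so the *mean* tip-to-tip distance between duplicate lineages
  equals the requested age (per-species depths differ, so realized
  outparalog ages vary around it — as they do in the data, where the
  ancient peak spreads over 0.6–0.7). WGD events duplicate every copy
  on their named lineage; tandem events duplicate one copy and place it
  at the adjacent gene-order index on the same chromosome, while all
  other duplicates relocate to a chromosome token unique to the event,
  so adjacency never arises by accident. Each duplicate-descended copy
  is lost independently per terminal lineage with probability 0.25 —
  enough attrition that, as in real genomes, outparalogs survive in
  only a subset of species, while the original copy always survives so
  no species drops out of a family.
* **Defaults.** 20 families of 300 codons, ω = 0.2 (strong purifying
  selection, typical of essential genes), one ancient duplication at
  dS 0.65, one Gm WGD at dS 0.1, one Mt tandem duplication at dS 0.04,
  seed-derived RNG streams per family (`seed + family_index`) for
  parallel-safe reproducibility.

Truth labels come from explicit gene-tree bookkeeping during
simulation: the most recent common ancestor node of two surviving
copies determines the relation (speciation node → ortholog; ancient
duplication → outparalog; WGD/tandem duplication → inparalog), the
true dS is the exact path length, and true dN is ω times it.

What passing recovery tests does and does not show: the simulator
shares its site-counting conventions with the estimator, so recovery
checks validate the pipeline's internal consistency, its label logic,
its tree reading and its landscape dating — not the adequacy of NG86
on real data with indels, rate variation and biased codon usage. The
external worked examples (soybean gene pairs with published Ks values)
are the appropriate check for that and are documented in the README as
an optional, network-requiring procedure.

## Numerical choices and degenerate inputs

* Distance saturation (p ≥ 3/4) is clamped just below the JC
  singularity for tree building, but reported as undefined in rate
  tables.
* `ng86` requires ten compared codons by default (configurable); fewer
  compared codons make site counts too noisy to interpret.
* Zero surviving complete-deletion columns is an error, not a silent
  empty result.
* NJ on two tips returns the single edge split evenly; equal-distance
  matrices yield a star with zero-length internal edges after clamping.
* Bootstrap on fewer than four tips returns empty supports (there is no
  internal bipartition to support).
* The peak detector returns no peaks for a flat histogram and treats a
  single-bin histogram's only bin as a peak when it holds any mass.

## Problem sizes

The shipped study conditions — 20 families, 300 codons, six species,
the three default events — are the sizes at which all bundled analyses
and checks run: they give roughly 260 sequences, 1500 within-family
pairs and 21 species-pair distributions, enough for every peak type to
be populated while a full pipeline run (with 200-replicate bootstraps
in the bundled checks; 1000 is the analysis default) completes in a few
minutes on one core.

## Worked example

```{r example, eval = FALSE}
library(KsScape)

cfg <- defaultPipelineConfig(seed = 1, n_families = 20, bootstrap = 200)
res <- runPipeline(cfg, out_dir = "ksscape_out")

res$evaluation$accuracy          # truth-label recovery
res$species_summary$closest      # closest species pair by lowest-Ks genes
subset(res$peaks, species_pair == "Gm-Gm")   # the WGD peak
res$selection$global_mean        # mean Ka/Ks across families
```

## Known limitations

* The search engine's seed requirement (one exact 11-mer) makes it
  blind to homologs below roughly 65–70% identity that happen to lack a
  conserved word — irrelevant after the 70% filter, but worth knowing
  if the thresholds are relaxed.
* The two-cluster rule detects at most one pre-speciation duplication
  per family; nested ancient duplications fold into one split.
* Tandem detection is adjacency-only; a relocated tandem pair or an
  inserted intervening gene defeats it, and the package exposes both
  the adjacency and the orthology evidence rather than adjudicating
  conflicts automatically.
* Reconciliation-based orthology (gene tree versus species tree) is
  out of scope.
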