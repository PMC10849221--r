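---
title: "Predicting bacterial protein expression from sequence: the riboflux pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bacterial protein expression from sequence: the riboflux pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboflux)
library(dplyr)
```

## The problem

How much protein a bacterial gene produces is shaped at several stages:
how often a ribosome loads onto the transcript (initiation), how fast it
moves across the codons (elongation), whether ribosomes queue behind slow
codons (traffic), and how long the finished protein survives
(post-translational stability). `riboflux` predicts per-gene protein
output in *E. coli*-style bacteria from sequence alone, in four stages:

1. a **biophysical translation-rate engine**: Shine-Dalgarno (SD)
   initiation-rate energetics, per-codon elongation rates from a dwell-time
   table, and a stochastic TASEP (totally asymmetric simple exclusion
   process) simulation of ribosome traffic;
2. an **eleven-feature extractor** for mRNA- and protein-level predictors;
3. a **learned translation rate** ("New_TR"): a regressor trained on the
   two biophysical rates against measured protein abundance (PA) or PA per
   mRNA, with six model families (linear, ridge, lasso, elastic net,
   random forest, RBF-kernel SVR), evaluated by Spearman rank correlation;
4. an **exhaustive feature-combination search** that augments New_TR with
   every subset of the ten remaining features and reports the best subset
   per size.

A synthetic operon/expression generator supplies data with the same
statistical structure, so every stage is testable without downloads.

## Data preparation

CDS sequences enter through a protein-coding filter: a standard start
codon (ATG/CTG/GTG/TTG), length a positive multiple of 3, no internal
stop, and a terminal stop codon. The terminal-stop rule is ours — the
stop-codon type is a model feature, so a CDS without one cannot be typed;
rejections carry machine-readable reasons. Non-ATG initiators translate to
methionine (the biological convention; it matters for the N-end feature).
Genes missing operon annotation are kept as single-gene operons with an
empty UTR, with UTR-dependent features flagged missing.

Expression tables are reduced to two responses. Replicate columns are
averaged per condition, condition columns are quantile-normalized
(average-ties dialect; the normalization itself is delegated to limma's
implementation behind the package's surface), and the per-gene mRNA value
is the arithmetic mean over conditions — aggregation before normalization,
which is the natural reading of "means of all conditions then normalized"
when replicates share a condition. Genes with zero protein or mRNA are
removed, and PA/mRNA is the exact ratio.

## The translation-rate engine

**Initiation.** The rate is Boltzmann-weighted in a total interaction
energy, `alpha = A_scale * exp(-dG_total / RT)` with `RT = 0.6156`
kcal/mol (37 °C) and three terms:

* *anti-SD hybridization*: the 16S rRNA tail 3'-UCCUCC-5' is slid across
  every hexamer in the −20..−5 window (+1 = first start-codon nucleotide;
  there is no position 0); per-pair pseudo-energies are G:C −1.5, A:U
  −1.0, G:U −0.5 kcal/mol, so a perfect AGGAGG scores −8;
* *spacing*: a quadratic penalty `0.25 * (spacing − 5)^2` kcal/mol on the
  spacer between the hexamer and the start codon, optimum 5 nt;
* *unfolding*: structure around the start codon opposes loading; the cost
  is `0.1 * (−MFE)` of the −35..+35 window.

`A_scale` is calibrated so a perfect SD at optimal spacing in an
unstructured UTR gives exactly 1 initiation per second. These constants
are package defaults standing in for a simulator whose internal
parameterization is not published; all are exposed in
`init_energy_params()`. With these defaults, sequences carrying a
consensus SD fall in roughly the 0.01–1 s⁻¹ range while SD-less sequences
fall many orders lower (about 10⁻⁸–10⁻³ s⁻¹) — the two clusters expected
for this kind of energetics model. The unfold weight (0.1) was set to
place the two clusters on those scales. UTRs shorter than the 20-nt
search window cannot support the calculation and are discarded with
reason `RBS_TOO_SHORT` before any modelling.

**Elongation.** Each codon's hop rate is the reciprocal of its dwell time.
The packaged dwell table is inversely proportional to the codon's tAI
weight, rescaled to a mean dwell of 0.05 s (20 codons/s, a typical
bacterial translocation speed). The gene-level elongation rate is the
harmonic-mean speed `L / sum(dwell)`; an arithmetic alternative would
ignore that slow codons dominate transit time.

**Traffic.** `tasep_simulate()` runs an exact continuous-time kinetic
Monte Carlo simulation of an open lattice of L codon sites with extended
ribosomes (footprint 10 codons by default, the literature-standard
ribosome footprint; configurable). Initiation requires the first
`footprint` sites vacant; a ribosome hops forward at the rate of its
A-site codon (A-site = leading edge − footprint + 1, clipped at 1; a
leading-edge indexing convention is available by flag) when the next site
is free; termination at rate β = 10 s⁻¹ (non-limiting) frees all sites
once the A-site reaches the last codon. Burn-in defaults to `10 L /
mean(k)` and measurement to `50 L / mean(k)` model seconds, empirically
sufficient for flux stabilization at these sizes; the flux standard error
comes from 20 batch means, and a split-half diagnostic warns (never
fails) if the two halves disagree by more than 3 combined SE. Identical
seeds give bit-identical trajectories.

`exact_steady_state()` is the validation oracle: it enumerates every
admissible ribosome configuration of a small lattice, builds the full
generator matrix, and solves the stationary distribution. The test suite
holds the simulator to this oracle (64-state system and a 9-point
boundary-rate grid, 3-SE agreement), to the low-density analytic current
`alpha (1 − alpha)`, and to the extended-particle maximal-current value
`1/(1 + sqrt(l))^2`. That last value is a thermodynamic-limit statement;
finite lattices sit measurably above it, so the bound check runs at
L = 900 codons where the asymptotic regime holds.

## Features

The eleven model features are: operon position (`Type`, first gene or
not), upstream AUG class (`uAUG`: none / in-frame / out-of-frame within
−12..−3; the −12 window follows the analysis convention, with the
10-base variant available via `uaug_window`), start- and stop-codon type,
CAI, tAI, the +1..+30 folding energy, protein length (amino acids —
nucleotide length differs by a constant factor and Spearman is
insensitive to it), N-end half-life class, instability index, and New_TR.

CAI uses Sharp–Li relative adaptiveness with a 0.5 pseudo-count for
unseen synonyms; the reference set defaults to the input CDS set itself
(self-referential usage) since no curated highly-expressed reference can
be assumed, and a user-supplied reference is accepted. tAI combines tRNA
gene copies with wobble penalties (G:U 0.41, I:C 0.28, I:A 0.9999, U:G
0.68, lysidine C:A 0.89); because real copy numbers are organism data the
package cannot assume, the packaged table is a synthetic stand-in with an
E. coli-like anticodon inventory and representative magnitudes — supply a
measured table for organism-accurate values. The elongation dwell table
is derived from these weights, so tAI and the elongation rate are
deliberately related quantities (as they are in real data, where both
reflect tRNA supply).

Folding energies default to a deterministic Nussinov base-pair
maximization (minimum hairpin loop 3, −1 kcal/mol per pair): a
reproducible, dependency-free pseudo-MFE that preserves the ranking
"more pairable → more structured". A thermodynamic nearest-neighbor
backend (`"vienna"`) shells out to RNAfold when available. Candidate MFE
windows are dropped entirely when more than 15% of genes cannot cover
them (short UTRs); missing values are never imputed. With 20–40-nt UTRs
the −30..−1 window typically exceeds the threshold while +1..+30 is
always covered.

The N-end rule classifies the residue exposed after N-terminal methionine
excision (excision when residue 2 is A/C/G/P/S/T/V): L/F/W/Y/R/K →
half-life under 2 minutes, proline → excluded (kept as a third
categorical level in modelling), all else → over 10 hours. A consequence
of this excision policy is that the destabilizing class only arises under
`met_excision = "always"`, since the small excision residues are all
stabilizing; the default therefore produces stable/excluded classes. The
instability index is the standard dipeptide-weight statistic
`(10/L) * sum DIWV(x_i, x_{i+1})` (> 40 predicts instability in vitro).

Categorical features are one-hot encoded with the most frequent level as
reference, and each categorical enters or leaves the subset search as one
atomic block.

## New_TR and the subset search

The two biophysical rates are the only inputs to New_TR: log10(alpha)
(it spans many decades) and the gene elongation rate, z-scored on
training statistics. The response is log10-transformed before fitting —
abundances span decades and squared-error fits would otherwise be
dominated by the top tail; Spearman evaluation is invariant to the
transform, so reported correlations are unaffected. The split is 80:20
(`round(0.8 n)` training genes), deterministic in the seed; genes
discarded for short RBS never enter the split. Each family runs with
fixed, documented defaults (no hyperparameter search, matching a
single-fit protocol): glmnet λ of 0.1 (ridge) and 0.01 (lasso / elastic
net with mixing 0.5), 500 trees, SVR with RBF kernel, cost 1, gamma
1/p, epsilon 0.1. Separate fits are made per target (PA and PA/mRNA),
since both are reported.

The search fixes one shared train/test split for all 1024 subsets of the
ten optional features (scores are only comparable on a common split),
trains New_TR plus each subset's encoded block, records the per-size
argmax of test-set Spearman with ties broken by enumeration order, and
re-evaluates winners on the full dataset. SVR over all 1024 subsets is
minutes-scale at a few thousand genes; the `k_range` argument (the
`--max-k` CLI flag) caps the search, and any family can drive it — the
bundled recovery analyses run the search with the linear family, which
is two orders of magnitude faster and recovers planted structure equally
well.

## The synthetic generator

`generate_genes()` emulates the sequence structure the pipeline assumes:
operons with geometric sizes; 20–40-nt A-rich UTRs (A 40%, G 25%, T 20%,
C 15%) carrying the AGGAGG consensus at spacing 5–7 nt with probability
`sd_strength` (so the motif sits about six nucleotides upstream of the
start, G-rich around −12..−7); CDS of 60–900 nt with start-codon usage
ATG/GTG/TTG = 90/7/3% and stop-codon usage TAA/TGA/TAG = 70/20/10%
(matching the dominance of ATG and TAA in real annotation), and body
codons tilted exponentially toward high-adaptiveness codons
(`codon_bias`). Every record passes the protein-coding filter by
construction.

`generate_expression()` plants effects on *features*, not on mechanistic
translation: log10 PA is a linear combination of standardized monotone
feature scores plus Gaussian noise, which makes recovery by the ML stage
analytically checkable. The default configuration — coefficients 1.5 on
log-initiation and elongation rate, 0.3 on Type/Start/Stop/Length, noise
SD 0.15, ~2000 genes from 1000 operons — makes the biophysical rates
carry most of the signal (as New_TR presumes) with secondary sequence
effects for the search to find. mRNA is log-normal with correlation 0.6
to PA, measured as two conditions × three replicates with 10%
replicate noise. A second, `"mechanistic"` mode routes expression through
the TASEP flux itself and is used for integration tests.

What passing on synthetic data does *not* show: real expression is not a
linear function of standardized features; real UTRs have correlated
composition, real codon usage reflects selection and mutation bias
jointly, and measured abundances carry heavy-tailed, gene-specific error.
Synthetic recovery demonstrates the machinery is correct and sensitive,
not that the same correlations will be reached on real data.

## Numerical choices and edge cases

* Quantile normalization: ties receive the mean of the reference values
  they span (average-ties dialect).
* Spearman on a constant vector is undefined: `NA` with a warning, never
  a silent zero. A fully shrunk lasso predictor is constant and is
  treated as carrying no signal.
* The pooled-variance t-test errors on zero pooled variance; Welch's
  variant is a flag.
* The exact TASEP solver refuses state spaces beyond ~2·10⁴
  configurations; simulation seeds derive deterministically from the base
  seed plus the gene index.
* Subset-search ties resolve to the lexicographically first subset
  (enumeration order), making reports reproducible.
* One-hot levels absent from a training split are dropped from that fit
  (constant columns carry no information and break standardization).

## Problem sizes used in the bundled analyses

The validation suite solves the exact oracle at L ≤ 10, compares the
simulator on L = 6 (deep runs and a 9-point boundary grid), checks the
low-density law at L = 200 and the maximal-current bound at L = 900, and
runs recovery on ~2000-gene synthetic datasets across 20 seeds with the
SVR New_TR and a linear-family search at subset size 4. These sizes were
chosen to keep every analysis on a single CPU at interactive timescales
while leaving Monte-Carlo error well below the tested tolerances.

## Known limitations

* The energetics constants are defaults of this package, not fitted
  thermodynamic parameters; absolute initiation rates are meaningful only
  relatively.
* The Nussinov pseudo-MFE overestimates pairing relative to
  nearest-neighbor models; it is a ranking device, and the ViennaRNA
  backend should be preferred when absolute kcal/mol matter.
* The packaged tRNA copy table is synthetic; tAI magnitudes (not the
  machinery) depend on supplying real copy numbers.
* The Met/Ile CAT-anticodon ambiguity is resolved generically (lysidine
  penalty term for AUA); organisms with unusual decoding need a custom
  wobble table.
* No cross-validation or hyperparameter search: the package mirrors a
  single-fit protocol; scores on small test splits carry the usual
  sampling variance.
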