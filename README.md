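# riboflux

Sequence-based prediction of bacterial protein expression: a biophysical
translation-rate engine (Shine–Dalgarno initiation energetics, per-codon
elongation rates, stochastic TASEP ribosome traffic), an eleven-feature
mRNA/protein feature extractor, a learned translation rate ("New_TR") with
six regressor families, and an exhaustive feature-combination search
evaluated by Spearman rank correlation — plus a synthetic operon/expression
generator so the whole pipeline runs and is tested without external data.

## Who this is for

Researchers modelling translation efficiency in *E. coli*-style bacteria:
predicting protein abundance (PA) or protein abundance per mRNA (PA/mRNA)
from sequence, dissecting which sequence features carry the signal, or
simulating ribosome traffic on a single mRNA.

## The model in brief

**Initiation** is Boltzmann-weighted in a total interaction energy,

```
alpha = A_scale * exp(-dG_total / RT),   RT = 0.6156 kcal/mol
dG_total = dG_duplex(anti-SD 3'-UCCUCC-5' vs best hexamer in -20..-5)
         + 0.25 * (spacing - 5)^2
         + 0.1 * (-MFE of the -35..+35 window)
```

with `A_scale` calibrated so a perfect, unstructured Shine–Dalgarno site
initiates once per second. **Elongation** converts per-codon dwell times
into hop rates (`k = 1/dwell`; gene rate = harmonic-mean speed `L/Σdwell`).
**Traffic** is an exact kinetic Monte Carlo simulation of the ℓ-TASEP
(extended ribosomes, footprint 10 codons, hard-core exclusion, open
boundaries); the steady-state termination flux is the translation rate, and
a master-equation solver provides exact currents on small lattices as the
validation oracle. **New_TR** re-learns the mapping from `(log10 alpha,
elongation rate)` to measured expression with any of six regressors
(linear, ridge, lasso, elastic net, random forest, RBF-SVR; 80:20 split,
Spearman scoring), and the **subset search** combines New_TR with all 1024
subsets of the ten remaining features (operon position, uAUG class,
start/stop codon, CAI, tAI, +1..+30 folding energy, length, N-end class,
instability index) on one shared split.

## Worked example

```r
library(riboflux)
library(dplyr)

cfg   <- synth_config(n_operons = 150, seed = 42)   # ~280 genes
genes <- generate_genes(cfg)
expr  <- generate_expression(genes$records, cfg)

resp <- expr$mrna_table |>
  aggregate_replicates(expr$grouping) |>
  quantile_normalize() |>
  (\(m) build_response(expr$pa_table, m))()
head(resp, 3)
#>   gene_id      pa  mrna pa_per_mrna
#> 1 g00001  328189. 106.        3092.
#> 2 g00002   29993.  87.6        342.
#> 3 g00003   75474.  65.2       1158.

fit <- fit_new_tr(expr$rates, resp, model_spec("SVR_RBF", seed = 1, target = "PA"))
fit
#> New_TR fit [SVR_RBF -> PA]: Spearman test 0.9401, total 0.9561 (n = 224/56 train/test)

ft <- build_feature_table(compute_features(genes$records), expr$rates, resp) |>
  add_new_tr(fit)
sr <- search_best(ft, model_spec("LINEAR", seed = 1, target = "PA"), k_range = 0:4)
tidy(sr)
#>       k subset                         spearman_test spearman_total
#> 1     0 ""                                     0.940          0.956
#> 2     1 "Start"                                0.952          0.962
#> 3     2 "Start+Length"                         0.960          0.965
#> 4     3 "Type+Start+Length"                    0.970          0.971
#> 5     4 "Type+Start+MFE_p1_p30+Length"         0.970          0.971
```

Reading the output: the SVR New_TR alone ranks genes by expression with
Spearman 0.94 on held-out genes (the generator plants most of its signal
on the two biophysical rates); adding sequence features the generator also
planted (start codon, length, operon position) raises the test-set score,
and the per-size table shows where gains saturate.

Single-mRNA traffic simulation:

```r
sim <- tasep_simulate(rate_profile("demo", alpha = 0.5, hop_rates = rep(10, 120),
                                   beta = 10, footprint = 10), seed = 1)
sim
#> TASEP simulation [demo]: flux 0.33 /s (SE 0.014), 198 terminations, 998 collisions
autoplot(sim)          # ribosome density profile along the mRNA
```

Real data enter through `read_fasta()` (CDS), `read_operon_table()`
(gene/operon annotation with 5'-UTRs) and `read_expression_table()`
(tab-separated expression matrices); `inst/cli/riboflux.R` wraps the
whole pipeline (`synth` and `pipeline` subcommands) for shell use.

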