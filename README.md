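# mamutkit

Analysis toolkit for **mutation-accumulation (MA) experiments** in clonally
propagated diploids — the *Daphnia pulex* style design in which tens of
lines descended from one heterozygous ancestor are pushed through
single-individual bottlenecks for ~100 generations, whole-genome sequenced
at ~12x, and assayed for life-history traits. It is aimed at researchers
estimating per-generation mutation parameters and their response to
treatments (e.g. chronic metal exposure) from such designs.

## What it computes

**Genomic stages.** From a per-site, per-line allele read-count table:

* callable-site masks (focal depth >= 6 reads, >= 1 read in every other
  line; LOH-callable additionally requires stretches >= 200 bp with gaps
  <= 6 bp), the denominators `C_i` of all rates;
* de novo SNMs, MNMs (SNM clusters within one 50 bp stretch) and small
  (< 50 bp) INDELs, by single-divergent-line candidate detection plus exact
  binomial consistency filters (focal count vs its genotype; every other
  line's count vs sequencing error);
* loss-of-heterozygosity events from Het-Hom site runs (>= 2 sites,
  >= 200 bp, no interior het evidence), with min/max/average size bounds,
  multi-scaffold merging via a chromosome map, and gene-conversion vs
  hemizygous-deletion classification by standardized relative coverage
  (threshold 0.75);
* rates: per line `n/(C_i g_i)` and pooled `sum(n)/sum(C_i g_i)` — plus a
  sensitivity-corrected rate over the effective denominator
  `C_eff = sum_s P(detect | depth)`, which removes the detection bias any
  strict filter chain has at 12x (see the methods vignette);
* spectrum statistics over the six collapsed substitution types with
  AT-content-corrected expectations (chi-squared, df = 5), treatment
  homogeneity (df = 15 for four treatments), ANOVA / Kruskal-Wallis
  treatment tests.

**Life-history stages.** Partial life tables per line/subline; the
intrinsic rate of increase r as the Euler-Lotka root
`sum_x e^(-rx) l_x m_x = 1` (with a stochastic projection cross-check);
mutational bias ΔM by weighted regression anchored at the non-MA population
mean; CV_m, ΔCV_m, V_M/V_E and broad-sense H² from one-way ANOVA variance
components; treatment x generation interaction, per-treatment line
divergence (Tukey HSD) and Bartlett variance tests.

**Synthetic data.** `sim_config()` + `simulate_ma_experiment()` generate
complete experiments (diploid ancestor at 0.7% heterozygosity, planted
SNM/MNM/INDEL/LOH truth sets, Poisson 12.4x read counts with miscalls,
trait decline with among-line variance) with recorded ground truth, so
every stage is verifiable without external data.

## Worked example

Published-scale aggregate arithmetic:

```r
library(mamutkit)
line_gens <- 28 * 82.3 + 27 * 120.5          # 5557.9 line-generations
per_line_snm_rate(644, 72163836, line_gens)  # 1.606e-09  -> "1.61e-9 /bp/gen"
67 / line_gens                               # 0.01206    -> "0.012 events/gen"
100 * 24 / 644                               # 3.73       -> "3.7% of SNMs in MNMs"
100 * chance_same_chromosome(3, 12)          # 0.694      -> "0.7%"
```

End-to-end synthetic run:

```r
run <- load_config(NULL)           # all defaults: alpha 0.05, eps 0.01, ...
run$seed <- 42L
run$sim <- list(n_scaffolds = 2L, scaffold_lengths = 100000L,
                treatments = ma_treatments(labels = c("Control", "Ni"),
                                           n_lines = c(6L, 6L),
                                           gen_mean = c(82.3, 120.5),
                                           gen_sd = c(4.7, 10.4)),
                mu_snm = 5e-7, loh_rate = 0.02,
                n_sublines = 4L, n_anchor_lines = 6L)
res <- run_report(run, out_dir = "ma_run")
```

prints (stage logs, then the summary written to `ma_run/summary.txt`):

```
mamutkit 0.1.0 report (config 308d2bbc33421226b22029b50e872ff4)
lines: 12; mean callable 192303 bp (SNM), 199558 bp (LOH); AT 0.5027
calls: 103 SNM, 0 INDEL, 21 LOH events
pooled SNM rate: 4.38e-07 /bp/gen (sensitivity-adjusted 5.81e-07)
LOH: 0.01721 events/gen, 440.9 bp/gen, 0.00221 /bp/gen
spectrum chi2(df=5) = 52.92, p = 3.5e-10
life history: r anchor 1.295, overall dM -0.004415 %/gen
```

Reading this: 103 SNMs were called across 12 lines; the raw pooled rate
(4.4e-7) underestimates the planted 5e-7 because a strict filter chain at
12x coverage misses ~1 in 4 heterozygous mutations, and the
sensitivity-adjusted estimate recovers it (here within Monte-Carlo noise of
a small genome); 21 LOH events give 0.017 events per line-generation; the
spectrum rejects uniformity (the generator's transition bias); the anchor
population's mean r is ~1.30 per brood interval and the overall mutational
bias ΔM is a fraction of a percent per generation. `ma_run/` also contains
the site-call table, truth JSON, per-line call summary, `loh.bed`/`loh.tsv`
and `report.json`.

A command-line wrapper covers the same stages:

```sh
inst/exec/ma-mutkit simulate --config cfg.json --out dir --seed 7
inst/exec/ma-mutkit call-snm --config cfg.json --out dir
inst/exec/ma-mutkit call-loh --config cfg.json --out dir
inst/exec/ma-mutkit rates    --config cfg.json --out dir
inst/exec/ma-mutkit lifehist --config cfg.json --out dir
```

## Documentation

The methods vignette (`vignettes/mamutkit-methods.Rmd`) describes the
statistical model, the synthetic world and its limits, the genotype-caller
calibration and sensitivity correction, LOH conventions, and known
small-sample caveats.
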