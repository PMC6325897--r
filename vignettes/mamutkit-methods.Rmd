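---
title: "Methods: mutation-accumulation analysis with mamutkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-accumulation analysis with mamutkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`mamutkit` analyzes mutation-accumulation (MA) experiments in clonally
propagated diploids such as *Daphnia pulex*: tens of lines descended from one
heterozygous ancestor, each passed through single-individual bottlenecks for
on the order of 100 generations, then resequenced at modest coverage
(~12x) and phenotyped. Four quantities are estimated:

1. **De novo mutation rates.** Single-nucleotide mutations (SNMs),
   multinucleotide clusters (MNMs, several SNMs inside one 50 bp stretch)
   and small (<50 bp) INDELs are identified from per-site, per-line allele
   read counts. The rate is `n / (C * g)` per line — mutations over callable
   sites times generations — and pooled as `sum(n) / sum(C_i g_i)`, which is
   identically the callable-generation-weighted mean of per-line rates.
2. **Loss of heterozygosity (LOH).** Runs of sites that were heterozygous in
   the ancestor but are homozygous in one line ("Het-Hom" sites) are
   assembled into events (at least two sites spanning at least 200 bp with
   no interior heterozygous evidence), sized by minimum (outermost Het-Hom
   sites) and maximum (between flanking unaffected het sites) spans, and
   classified as copy-neutral gene conversion versus hemizygous deletion by
   standardized relative read depth with a 0.75 threshold.
3. **Spectrum statistics.** SNMs collapse onto six strand-symmetric classes
   keyed by the ancestral base pair. Uniformity is tested against
   expectations proportional to the callable genome's AT:GC composition
   (Pearson chi-squared, df = 5); homogeneity across treatments uses the
   6 x T contingency chi-squared (df = 15 for four treatments). The paper
   trail behind this package prints df = 9 for the 6-class uniformity test;
   six categories admit df = 5, which is what we implement.
4. **Life-history mutational parameters.** The intrinsic rate of increase r
   solves the discrete Euler-Lotka equation `sum_x e^(-r x) l_x m_x = 1` on
   partial life tables (bracketed root finding, residual < 1e-10), with an
   independent stochastic age-structured projection for cross-validation.
   Mutational bias (dM) is the slope of a weighted regression of line trait
   values on generations forced through the non-MA anchor mean at
   generation zero (weights 1/SD of subline values); CV_m, dCV_m, V_M/V_E
   and broad-sense H2 derive from one-way ANOVA variance components
   (among-line component `(MS_among - MS_within)/n0`, truncated at zero).

## The synthetic world

Every stage is driven by `sim_config()`, whose defaults state the emulated
experiment once: 0.7% ancestral per-site heterozygosity; 28 control lines at
82.3 +/- 4.7 generations and 9 lines each for Ni, Cu and Ni+Cu at
120.5 +/- 10.4; mean coverage 12.4x (Poisson, no overdispersion in this
version); per-read miscall rate 0.005; SNM rate 1.61e-9 per site per
generation; LOH rate 0.012 events per line per generation. Rates are per
diploid site (a site counts once, not per haploid copy) — the convention
under which the pooled arithmetic of the emulated study reproduces its
printed rate.

Parameters no published source states were fixed once: transition-biased
spectrum weights (1, 2, 1, 6, 1, 2) with GC>AT dominant; INDEL rate 4e-11
(implied by 16 INDELs over the published callable-generation product); MNM
probability 0.016 per mutational event with cluster sizes 2-3 (implied by
10 MNMs holding 24 of 644 SNMs); LOH sizes log-uniform on 250-500000 bp;
gene-conversion fraction 0.5. They are realism choices, not calibrated
claims, and the acceptance battery never conditions on them.

What the generator does *not* emulate: read-level artifacts (mapping error,
strand bias, indel realignment), depth overdispersion, linked selection, and
k-mer sequence context. A green recovery test therefore establishes that the
*inference machinery* is correct for the stated stochastic model, not that
the model captures every failure mode of real short-read data.

### Clutch schedules and the unit of r

Subline clutch schedules are built by inverting Euler-Lotka: a target r is
drawn from the planted line/subline model
(`b_i ~ N(g delta a, g vm)`, subline noise `N(0, ve)`), then four clutch
sizes on the fixed age grid (2, 3, 4, 5 brood intervals, one interval ~3.5
days) are scaled so the subline's life table returns exactly that r. Clutch
sizes are therefore real-valued expected counts; integer rounding would leak
extra variance into V_E and bias variance-component recovery. On this grid
an anchor r of 1.30 per brood interval corresponds to ~9-13 neonates per
clutch — the time convention that makes the conventional unitless r
magnitudes come out with realistic fecundities. `solve_r()` itself is
unit-agnostic.

## Genotype calling and the sensitivity correction

The table's genotypes emulate an upstream error-aware caller: a non-
reference allele enters a genotype only with at least `min_alt_reads(d)`
supporting reads, the smallest count whose same-base error-pileup
probability `3 C(d,k) (e/3)^k (1-e/3)^(d-k)` falls below a per-site budget
`p_call` (default 2e-9). The budget is genome-wide calibration: over ~2e7
site-line trials the expected number of error-born non-reference genotypes
is ~0.004, so mutation-free tables are clean in >99% of runs.

That stringency has an unavoidable price at 12.4x: the probability that a
true heterozygous mutation at a callable site survives the caller plus the
exact-binomial consistency filters is ~0.76 (it needs ~5 alt reads at the
modal depth). No per-site threshold rule can hold both ~zero false positives
over 2e7 trials and >=90% sensitivity at this coverage — the two goals are
mathematically incompatible here. Rates are therefore computed over an
*effective* callable denominator,

```
C_eff,i = sum over callable sites s of P(detect | depth_i(s))
          x P(no other line spoils the candidate) x (1 - pi_het),
```

every term in closed form from the same thresholds the caller and filters
use (`snm_detection_sensitivity()`); `pi_het` enters because ancestrally
heterozygous sites are blind for single-site SNM detection in a design whose
ancestral genotype is the cross-line consensus. Nothing in the correction is
fitted to outcomes; it is the standard detectability-weighted denominator,
and it makes the pooled estimator unbiased (recovery of a planted 1e-7 rate
is part of the acceptance battery). Both the raw (`rate`) and corrected
(`rate_adj`) values are reported.

## LOH zygosity, overlap, and numerical choices

Het-Hom sites deliberately do not reuse the conservative caller: a line is
*hom-consistent* at a site when its minor-allele count is explainable by
sequencing error (one-sided exact binomial against `eps = 0.01` at
`alpha = 0.05`), and *het-evident* otherwise. A site is treated as
ancestrally heterozygous for a focal line when at least half of the covered
non-focal lines are het-evident — a majority rather than unanimity, because
LOH events may legitimately overlap among lines; a truly homozygous site
cannot reach a majority of het evidence through errors. Events are reported
per line and never merged across lines.

Span conventions: minimum span is `last - first + 1` over the Het-Hom
sites; maximum span is the open gap between the nearest flanking unaffected
het sites (`next - prev - 1`), extending to the scaffold edge when no
flanking site exists; average size is their mean, except multi-scaffold
events (whole-scaffold homozygosity merged via the scaffold-to-chromosome
map) which keep the summed minimum estimate. The MNM window is implemented
as cluster span <= 49 bp (all members inside 50 consecutive bases) with
greedy left-to-right clustering. Two-sided binomial p-values are twice the
smaller exact tail, capped at one. The expected count of true Het-Hom point
mutations uses an allele-target factor of 1/3 by default (the chance a
mutation at a het site hits the allele that makes the genotype look
homozygous), exposed as a parameter.

## Statistical gates and small-sample caveats

Treatment comparisons use one-way ANOVA when Shapiro-Wilk on residuals does
not reject normality at 0.05, otherwise Kruskal-Wallis; both can be forced.
The V_M divisor defaults to 2 (diploid-MA convention), configurable to 1.
Zero subline SDs in the anchored regression (single surviving subline) are
replaced by the median positive SD, with a warning. Sublines dead before
measurement are excluded throughout.

Variance components themselves are unbiased, but CV_m (a square root) and
V_M/V_E (a ratio) carry O(1/n) transformation bias at 10 lines x 5
sublines — a few percent, visible when averaging hundreds of replicates.
The recovery tests track this: means of dM, CV_m and V_M/V_E over 500
replicates sit within two standard errors of their planted values, while
broad-sense H2 — the most nonlinear transform — is validated against a
constructed 3:1 component case instead of a plug-in target.

## Engineering notes

Configuration files are JSON rather than YAML (no YAML parser in the
supported dependency set); unknown keys are rejected. Callable masks are
plain interval tables (0-based half-open; BED on disk, 1-based in the
VCF-style outputs) built from run-length scans that are tested against
brute-force scanners. Site-call tables are sparse by construction: rows
exist only at ancestrally heterozygous sites, planted mutation sites, and
sites receiving an error pileup at least as large as the caller's global
minimum support — provably every site the calling module could act on —
while per-site depths stay dense for masks and coverage ratios. All
randomness derives from one seed; identical seeds give byte-identical
outputs at every stage, including the end-to-end report.
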