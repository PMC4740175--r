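---
title: "Methods: non-CG methylation as a differentiation-capacity biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-CG methylation as a differentiation-capacity biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cphcap)
```

## The analysis problem

Pluripotent stem cell lines carry substantial cytosine methylation outside
the CpG context (CpH sites, H ∈ {A, C, T}), a mark that is nearly absent in
differentiated somatic cells. The analysis implemented here asks whether the
*global level* of CpH methylation, measured at the ~2,700 autosomal CpH
probes of a 450K-style array, separates lines with high endodermal
differentiation capacity (HDC) from lines with low capacity (LDC), and
whether a small probe panel can predict capacity for new lines.

The measurement unit is the beta value β ∈ [0, 1], the methylated fraction
of the cells assayed at one probe. Lines are measured as several replicate
DNA extracts; after QC, extracts are averaged so that the *cell line* is the
analysis unit.

## Synthetic cohorts: what they emulate, and what they do not

All tests run on cohorts from `simulate_cohort()`. The generative model is
logit-normal throughout:

* each CpH probe has a baseline θ_p ~ N(0, `probe_sd_logit`) on the natural
  logit scale (default SD 0.8, giving the broad per-probe spread of β seen
  on arrays);
* a group shift δ_g is solved by root finding (`uniroot`, tolerance 1e-8,
  bracket ±40) so that the *grand mean of β*, `mean(plogis(θ_p + δ_g))`,
  equals the target group mean — the calibration targets are means of β,
  not of logits;
* each line adds a scalar shift ~ N(0, `line_sd_logit` = 0.15) to its CpH
  probes only. This is the biological signal the biomarker exploits: lines
  differ in their *global* non-CG level. CpG probes deliberately receive no
  line or group effect, making the CpG compartment an exact null for group
  comparisons;
* each extract adds independent per-probe noise ~ N(0, `extract_sd_logit`
  = 0.10);
* CpG probes are bimodal: a fraction `cpg_meth_frac` = 0.70 around β ≈ 0.85
  and the rest around β ≈ 0.10 (probe-level logit SD 0.5);
* rs probes carry a per-line genotype in {0, 0.5, 1} (Hardy–Weinberg-like
  1:2:1 draw) shared by all extracts of the line, plus N(0, 0.01) noise;
* detection p-values are Uniform(0, 0.005) unless failures are injected;
* Infinium-I conversion controls: negatives ~ N(150, 15), converted
  controls ~ N(150 + 5000·c, 100), unconverted ~ N(150 + 5000·(1−c), 100),
  floored at 0, where c is the conversion rate (default 0.995).

Default design: 15 HDC + 10 LDC + 6 donor lines, 6 extracts per line, group
means 50% / 37% / 8%. The 15/10 split is an assumption — only the total of
25 discovery lines and the two phenotype classes are fixed by the study
design the generator emulates — and it is configurable. Donor lines are
assigned round-robin as the source of the hiPSC lines, so donors give rise
to lines of both phenotypes, which is what makes the donor-vs-donor
comparison a true null. The replication design (`replication_config()`) is
5 HDC + 5 LDC lines with 2 extracts each and no donors: the replication
cohort size (10 lines, ~20 extracts) is part of the emulated design, while
its class split is again an assumption. Passing the discovery cohort as
`template =` reuses the probe-level parameters, emulating a second cohort
measured on the same array — without this, a probe panel selected in one
cohort would be meaningless in the other.

What the generator does *not* emulate: raw two-channel intensities, dye
bias and within-array normalisation (data enter as β), cell-composition
heterogeneity, correlated probe blocks (probes are independent given the
line), batch effects (batch labels are assigned at random, making the SVD
scan a true null), and any real genomic coordinates (positions are uniform
over autosomes). Passing tests therefore demonstrate the *statistical
machinery* is correct at realistic effect sizes and noise levels; they do
not validate normalisation choices or probe-level genomic structure on real
arrays.

## Quality control

**Conversion efficiency.** Per sample,
`adj(X_i) = max(X_i − N̄, 0)` for the three converted (BIC) and three
unconverted (BIU) control intensities, with N̄ the mean negative-control
intensity; efficiency = `100 · Σ adj(BIC) / (Σ adj(BIC) + Σ adj(BIU))`
percent. The statistic is scale invariant. If both adjusted sums are zero
the sample is flagged degenerate rather than scored; by the formula the
statistic is 100 when only the unconverted side vanishes. The generator's
constants make the statistic an unbiased recovery of the configured
conversion rate to well under one percentage point at moderate sample
numbers.

**Detection filtering.** A detection p-value is the confidence that signal
exceeds background, so *large* values are failures: a probe with p > α
(default 0.01) in at least one extract is excluded. Exclusions are monotone
in α.

**Replicate outliers.** Sample swaps are detected on the rs genotype
probes: an extract is flagged when the majority of its k nearest neighbours
(Euclidean distance on rs-probe β) belong to a different line, with k equal
to the number of other extracts of its own line. The plain nearest-neighbour
rule (k = 1) is a special case; the majority vote is needed because a
swapped-in extract carries another line's genotype exactly, so members of
that source line would otherwise tie with it and be flagged spuriously.
Lines with a single extract cannot be checked and are reported as skipped.

**Probe exclusions.** Probes on chromosomes X/Y are excluded (mixed-sex
cohorts). With a variant table, probes whose target dinucleotide (positions
p, p+1 on the probe strand) overlaps a variant are flagged
`variant_at_target`, and probes with a variant in the 10 bases adjacent to
the target on the single-base-extension side (strand-aware) are flagged
`variant_3prime_10bp`. The true extension orientation would require the
array manifest; the adjacent-window approximation is documented here as
such. Each probe gets one primary reason code, in the priority order listed.

**SVD scan.** The β matrix is column-centred (per-sample means removed) and
decomposed; each of the top k right-singular vectors is tested against
sample covariates — Kruskal–Wallis for categorical, Pearson correlation test
for numeric — with constant covariates reported as missing. On the default
synthetic cohort the leading component tracks the phenotype groups and no
technical covariate associates with the top components, as expected from a
generator without batch effects.

## Differential methylation

Statistical testing is done on M-values, `M = log2(β/(1−β))`, after clamping
β to [ε, 1−ε] with ε = 1e-6 — the clamp keeps M finite without materially
moving interior values, and the logit scale removes most of the
heteroscedasticity of β near its boundaries. Because the generator is
logit-normal, M-values are exactly normal under the synthetic model, which
is what makes the moderated-t calibration testable.

Extracts are averaged to line level *before* testing, so the per-group
sample sizes are numbers of lines (the biological replicates), not extracts.
Per probe, the pooled two-group variance s²_g has d_g = n₁ + n₂ − 2 df.
The prior (d₀, s₀²) is estimated by moment matching the scaled-F marginal of
the s²_g on the log scale: with e_g = log s²_g − digamma(d_g/2) +
log(d_g/2), the mean of e estimates log s₀² and its excess variance over
trigamma(d_g/2) estimates trigamma(d₀/2), inverted by Newton iteration
(relative tolerance 1e-12). Non-positive excess variance yields d₀ = ∞ — the
homoscedastic limit, which is in fact the correct answer under the
generator, where every probe shares the same line/extract noise. The
posterior variance (d₀s₀² + d_g s²_g)/(d₀ + d_g) replaces s²_g in the t
statistic, which gains d₀ df (capped at the total residual df). Zero-variance
probes are excluded from prior estimation but still receive a finite
moderated t through the shrinkage. d₀ = 0 recovers the ordinary pooled t,
d₀ = ∞ a z-like statistic against s₀²; both limits are asserted numerically
in the tests, and the full estimator is cross-checked against an independent
implementation (limma) to 1e-6.

MVPs are called at BH-FDR 0.05; direction is *hyper* when the HDC mean beta
exceeds the LDC mean. The group-level summary `group_delta()` uses a Welch
(unequal-variance) two-sample t on line-level mean β — the unequal-variance
form is an assumption, chosen because the two phenotype groups have no
reason to share a variance. Degenerate inputs (a constant pair of groups)
return the exact difference with p = 1 rather than erroring. Donor
("epigenetic memory") deltas are per matched line–donor pair, summarised by
phenotype group.

Per-motif summaries group CpH probes by their 6-base flank; motifs with
fewer than 5 probes pool into "other". Note that per-probe Δβ varies
systematically with the probe baseline (logistic compression near 0 and 1),
so motif means scatter even under a motif-independent generator; the
motif-independence check is therefore a rank test of Δβ across motifs plus
direction concordance, not a raw bound on motif-mean differences.

## Resampling nulls

The permutation test permutes group labels over lines (the same unit as the
t-test), recomputing Δβ_mean each draw; the two-sided empirical p uses the
add-one estimator (1 + #{|null| ≥ |obs|})/(B + 1). Labels of the smaller
group are permuted, which makes the p-value exactly invariant to swapping
the group names at a given seed. When B reaches the number of distinct
assignments the test switches to exhaustive enumeration and reports the
exact proportion (the observed labelling counts itself, so p ≥ 1/N). Default
B = 20,000 at desk scale; larger values are a parameter, not a code change.

The Monte Carlo null draws `n_probes` CpG probes without replacement
(default 2,676, the CpH panel size) B = 10,000 times and records the group
Δβ_mean of each subset; the `beta_min = 0.80` variant restricts the pool to
methylated probes, reflecting the true genomic distribution of CpG
methylation. Because a subset's Δ is the mean of per-probe deltas, these are
precomputed once, making a draw O(n_probes).

## The nine-probe classifier

Significant MVPs are ranked by p; the panel is the k = 9 smallest-p probes
from the top-200 pool. (The original assay also screened probes for
pyrosequencing suitability, which is not computable here; an alternative
`spread` rule maximising pairwise Δβ separation is provided.) Per group, the
line-level panel means give a Student-t 95% CI — the CI construction over
line-level means is a documented choice — and the decision threshold is the
midpoint of the LDC upper and HDC lower bounds. Midpointing the *printed*
bounds 40% and 52% gives exactly 46.0%; a published threshold of 45.8%
corresponds to unrounded bounds, so this package always reports the
unrounded midpoint. Overlapping CIs still yield a model but are flagged
prominently. Prediction is the panel mean (pairwise-complete) against the
threshold with ties going to HDC — deterministic, and consistent with
reporting signed deviations; a line missing more than a third of the panel
is marked unpredictable rather than guessed.

## Clustering and the Reference Corridor

Lines are clustered agglomeratively (default Euclidean distance, average
linkage — the choice is configurable since no single convention exists) on
the significant probes, with columns pre-sorted by line id so ties resolve
deterministically. `clade_purity()` cuts at k (default 3: LDC, HDC, donor)
and reports per-class purity, overall majority-class agreement and the
adjusted Rand index.

Promoter methylation is the *median* β of a promoter's CpG probes (few
probes per promoter; the median resists outliers). A promoter×sample
estimate is captured when it lies within the promoter's published
[lower, upper] corridor, bounds inclusive; the denominator of the capture
rate is all promoter×sample estimates. Near-miss distances are measured in
absolute β units (the corridor bounds are fractions; a relative variant is
available via `relative = TRUE`), with fractions of missed estimates within
0.10 and 0.20 of a bound. CV = sample SD (n−1 denominator) divided by the
mean across samples; promoters with one usable sample or a zero mean are
flagged, not scored.

## Determinism and problem sizes

Every stochastic stage takes a seed; `run_discovery()` derives an
independent substream per stage from its master seed, so toggling one stage
never shifts another's draws. The test suite uses the full default cohort
(22,735 probes × 186 extracts) for the calibration and end-to-end checks,
scaled-down cohorts (~120–200 CpH probes, 8–13 lines, 2 extracts) for
property loops, 200 null cohorts at B = 300 for the permutation type-I
check, and B = 1,000 draws for the Monte Carlo bound — sizes chosen so the
whole suite runs in a few minutes while keeping each check's resolution
adequate for its tolerance.

## Known limitations

* The generator's independence of probes given the line means clustering on
  synthetic data is easier than on real arrays, where correlated probe
  blocks can create sub-clades; clustering results on synthetic cohorts are
  upper bounds on tidiness.
* Between-line variation is a single scalar per line; real lines also vary
  in profile shape (passage, culture adaptation), which would widen the
  group CIs relative to the simulation.
* The moderated t assumes extracts were averaged first; designs that model
  extracts directly (e.g. duplicate-correlation) are out of scope.
* The 3′-polymorphism window is an approximation of probe geometry without
  the array manifest.
* Epigenetic-clock ages are not computed; `attach_dnam_age()` only joins a
  user-supplied table of precomputed ages.
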