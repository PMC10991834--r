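---
title: "Cis Mendelian randomisation with cismr: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cis Mendelian randomisation with cismr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The problem

Whether perturbing a drug target changes disease risk can be asked
genetically: variants in or near the target's gene that alter a downstream
biomarker act as lifelong, randomly allocated "mini-trials" of target
modulation. `cismr` implements this *cis* (drug-target) Mendelian
randomisation design for summary data. The reference analysis asks whether
IL-6 signalling — proxied by C-reactive protein (CRP) associations of
variants in the *IL6R* gene region — affects the risk of pulmonary arterial
hypertension (PAH), combining three case-control GWAS sources: an
international case-control meta-analysis (2085 cases / 9659 controls), a UK
Biobank PAH GWAS (493 cases / 24 650 controls), and FinnGen round 9 (234
cases among 377 277 participants). The exposure associations come from a
CRP GWAS of 361 194 UK Biobank participants.

Restricting instruments to the target's own gene region is what licenses
the causal interpretation: a variant inside *IL6R* that changes CRP is
expected to do so through IL-6 signalling, not through the many other
pathways that genome-wide CRP variants tag.

## The estimator

For instrument $j$ with harmonised exposure association
$\hat\beta_{Xj}$ (SD units of the biomarker per allele) and outcome
association $\hat\beta_{Yj}$ (log-odds per allele), the variant-specific
Wald ratio is

$$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj},
  \qquad \mathrm{se}(\hat\theta_j) = \mathrm{se}(\hat\beta_{Yj}) / |\hat\beta_{Xj}|,$$

the first-order delta method, which ignores exposure-side uncertainty.
This is standard for strong instruments (the selected instruments here
have F-statistics in the tens to hundreds); a second-order SE that adds
the exposure term is available via `se_method = "delta2"`.

Within each study the ratios are pooled by fixed-effect inverse-variance
weighting (IVW) with weights $w_j = \mathrm{se}(\hat\theta_j)^{-2}$:

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
  \qquad \mathrm{se}(\hat\theta) = \Big(\sum_j w_j\Big)^{-1/2},$$

identical in form to a fixed-effect meta-analysis (and algebraically to
weighted least squares of the $\hat\theta_j$ on a constant — the identity
the test suite exploits as an independent oracle). The study-level
estimates are then pooled across GWAS sources by the same rule. Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ on $k-1$ degrees of freedom
measures between-variant heterogeneity within a study and between-dataset
heterogeneity across studies. Estimates are reported on both the log-odds
and the odds-ratio scale per unit (mg·L⁻¹) of the biomarker; all intervals
use the 1.96 normal quantile.

Fixed-effect pooling is the default because a single pooled estimate with
no indication of heterogeneity is the target of inference; a
multiplicative random-effects standard error (`random_effects = TRUE`)
never deflates the fixed-effect SE and is offered as a sensitivity
analysis. Weak residual correlation between clumped instruments
($r^2 \le 0.1$) is deliberately ignored in the weighting — the design
choice being to minimise the chance of missing a true effect rather than
to maximise precision — so the pooled SE can be mildly anti-conservative
when residual correlation is at the threshold.

## Instrument selection

1. **Window.** Variants on the region's chromosome with position inside
   the gene body ± `flank` bp, boundaries inclusive. "A 100-kb window" is
   interpreted as ±100 kb flanking the gene body — the usual cis-window
   convention — and is configurable.
2. **Significance.** Strict `p < threshold`, default the Bonferroni level
   `0.05 / 1000 = 5e-5` for the roughly 1000 variants a cis region of
   this size contains.
3. **Clumping.** Greedy: sort by ascending p-value (ties broken by
   variant ID so reruns are identical), keep the best remaining variant,
   discard everything remaining with $r^2$ above `r2_max` (default 0.1)
   against it, repeat. $r^2$ is the square of the signed correlation in
   the supplied LD matrix; the kept-set pairwise-$r^2$ postcondition is
   asserted on every run. No distance window and no conditional/joint
   modelling: the rule is purely $r^2$-based.

Strength diagnostics are computed on the *unadjusted* (observed) exposure
associations, because they describe the selection-time evidence: per-variant
$F = (\beta/\mathrm{se})^2$; variance explained
$\sum_j 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\beta_j^2$ assuming a
standardised exposure and independent variants (supply `trait_variance`
for an unstandardised exposure); and the equivalent-power sample-size
inflation $1/R^2$ — instruments explaining 1% of exposure variance imply
an MR study needs roughly 100 times an observational study's sample size.

## Winner's curse and FIQT

Selecting variants on `p < 5e-5` biases their exposure effect estimates
away from zero. The FDR inverse quantile transformation (FIQT) corrects
this by Benjamini–Hochberg-adjusting the two-sided p-values over the
selection context and mapping back through the normal quantile:
$z^{adj}_j = \mathrm{sign}(z_j)\,\Phi^{-1}(1 - p^{BH}_j/2)$, with
$\beta^{adj}_j = z^{adj}_j\,\mathrm{se}_j$ and standard errors left
untouched. Shrinkage ($|z^{adj}| \le |z|$) and rank preservation follow
from BH never decreasing a p-value; the implementation also enforces the
shrinkage bound numerically, which simultaneously guards the
back-transform where p-values underflow to zero in the far tail
(|z| ≳ 38).

Two design choices are open in principle and resolved as follows:

* **FDR context.** The adjustment is computed over the full pre-selection
  region table by default (`fiqt_context = "region"`), with the
  instruments' adjusted effects read off it, because the curse arises from
  region-wide selection; adjusting only the selected set
  (`"instruments"`) is available and the choice is echoed in the run
  manifest.
* **Which side is adjusted.** Only exposure associations — selection was
  on exposure p-values; outcome associations are untouched.
* **Order.** Clumping uses the unadjusted p-values and the correction is
  applied to the final table; since FIQT preserves p-value order, applying
  it before or after clumping selects the same variants.

The correction can be disabled (`fiqt = FALSE`) for sensitivity analysis;
tables carry both `beta` (adjusted) and `beta_unadjusted`.

## Harmonisation

Exposure and outcome associations are aligned to a shared effect allele:
direct match, allele swap (sign and frequency flip), strand flip
(reverse complement), or both. Palindromic variants (A/T, C/G) are the
ambiguous case — strand flipping is indistinguishable from allele
swapping — and are resolved by allele frequency: if either study's
effect-allele frequency lies inside the ambiguity band the variant is
excluded as `palindromic-ambiguous`; otherwise concordant sides of 0.5
confirm the label alignment and discordant sides imply the opposite
strand (an extra sign flip). The band default, `[0.42, 0.58]`, is a
conventional choice — the underlying requirement, "alignable by allele
frequencies", fixes no particular width — and is configurable and logged.
Indels and irreconcilable allele pairs are excluded (`non-SNP`,
`allele-mismatch`), as are variants absent from the outcome
(`missing-in-outcome`; no proxy lookup is attempted). Every exclusion is
reported with its reason. Palindromic variants lacking a frequency are
excluded; non-palindromic ones missing a frequency are kept with a
warning.

## The synthetic-data generator

`synth_config()` / `generate_region()` simulate the data-generating
process the estimator assumes, so calibration and recovery are testable
without any download:

* ~1000 variants in the *IL6R* cis window, MAF uniform on (0.05, 0.5],
  15% palindromic allele pairs, block-diagonal LD (blocks of 20 variants,
  within-block correlation 0.5, a final short block absorbing any
  remainder);
* 12 causal variants with per-allele exposure effects
  $N(0, 0.03^2)$ (SD units), propagated to marginal effects through the
  LD matrix (`marginal = R %*% joint`). The effect scale is the one free
  parameter the study conditions do not pin down directly; 0.03 was chosen
  once so that the default region yields on the order of a dozen selected
  instruments with mean F in the tens to hundreds, the scale of the
  reference analysis (12 instruments, mean F 92, ~1% variance explained);
* exposure estimates multivariate normal around the marginals with
  covariance $r_{ij}\,\mathrm{se}_i\,\mathrm{se}_j$ and
  $\mathrm{se}_j = (2\,\mathrm{maf}_j(1-\mathrm{maf}_j)\,n)^{-1/2}$
  (unit-variance trait, $n$ = 361 194);
* outcome marginal log-odds $\theta^*\times$ marginal exposure effect,
  plus optional direct (pleiotropic) variant effects shared across
  studies; standard errors use the effective sample size
  $n_\mathrm{eff} = 4/(1/n_\mathrm{cases} + 1/n_\mathrm{controls})$ of
  each of the three case-control designs. This standard approximation for
  summary-level simulation reproduces the dominant feature of the real
  data: the tiny case counts (down to 234) dwarf the exposure GWAS and
  dominate power.

What the generator does *not* emulate: individual-level genotypes,
realistic LD decay within blocks, allele-frequency differences between
studies, participant overlap between exposure and outcome samples, and
case-control ascertainment beyond the effective-sample-size
approximation. Passing calibration tests therefore demonstrates
correctness of the estimator under its own assumptions, not robustness to
those real-data complications.

## Numerical and degenerate-input choices

* p-values of exactly 0 on input are replaced by the smallest positive
  double (with a warning) so the FIQT back-transformation stays finite.
* A reported p-value must round-trip with $|\beta/\mathrm{se}|$ under the
  two-sided normal within a generous tolerance (0.1 absolute or 5%
  relative on the z-scale); rows failing this — or any other validity
  check — are rejected with a per-row reason, never silently dropped.
* Alleles are stored uppercase; lowercase input is normalised with a
  notice.
* A single pooled component leaves Cochran's Q undefined (`NA`) rather
  than 0.
* An analysis stage that empties the variant set terminates the pipeline
  gracefully with the stage named in the condition and the manifest.
* The analysis path contains no randomness and every tie-break is
  deterministic, so reruns on identical inputs are byte-identical (the
  manifest deliberately contains no timestamps).

## Problem sizes used in the test suite

The statistical acceptance checks run at the reference study sizes
(1000 variants, exposure n = 361 194, the three outcome designs): null
calibration uses 2000 simulated replicates (pooled 95% CI excluding zero
at the nominal 5%), effect recovery 500 replicates at
$\theta^* = 0.2$ (mean within 3 Monte-Carlo SEs), and the winner's-curse
demonstration 40 replicates of a weaker-effect configuration (60 causal
variants, effect SD 0.012) in which selection bias is material and FIQT
reduces it. Unit tests use smaller regions (12–300 variants) so the whole
suite completes in a couple of minutes.

## Known limitations

* One genome build is assumed throughout; coordinates are treated as
  opaque and must be consistent across inputs (no liftover).
* No MR-Egger, weighted-median or other pleiotropy-robust estimators: the
  cis design argues for exchangeability, and directional pleiotropy is
  not separately testable here.
* No correlation-aware (generalised) IVW; residual $r^2 \le 0.1$ is
  ignored by design.
* Odds ratios are per unit of the biomarker on its additive scale
  (mg·L⁻¹ for CRP); no conversion to or from per-log-unit scales is
  attempted.
* Sample overlap between exposure and outcome studies is neither modelled
  nor corrected; overlapping samples make estimates overly precise.
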