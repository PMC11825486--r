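---
title: "Methods: two-sample MR and two-step mediation from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The model

Two-sample MR works from per-variant summary associations. For variant
$j$, let $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ be its estimated
effect on the exposure and $\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j,
\sigma_{Yj}^2)$ its estimated effect on the outcome, with $\theta$ the
causal effect of interest and $\alpha_j$ a possible direct (pleiotropic)
effect. A valid instrument has $\alpha_j = 0$, is associated with the
exposure, and is independent of confounders. The package's estimators are
different ways of combining the per-variant Wald ratios
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ under different assumptions
about the $\alpha_j$.

For mediation, a second trait $M$ sits on a path $X \to M \to Y$. With
$a$ the effect of $X$ on $M$, $b$ the effect of $M$ on $Y$ conditional on
$X$, and $c$ the direct effect of $X$ on $Y$, the total effect is
$c + ab$, the mediated effect $ab$, and the proportion mediated
$ab/(c+ab)$. The two-step procedure estimates BETA1 $= \hat a$ by
univariable MR of $M$ on $X$'s instruments, BETA2 $= \hat b$ as the
mediator's conditional effect in a multivariable IVW of $(X, M)$ on $Y$,
and BETA as the univariable total effect, then applies the exact algebra
`mediation = BETA1*BETA2`, `direct = BETA - BETA1*BETA2`,
`proportion = BETA1*BETA2/BETA`. Both steps are gated at nominal
$p < 0.05$; a failed gate is reported as a labelled
mediation-not-supported outcome, not an error.

# Harmonization and instrument selection

Effect alleles differ between GWAS files, so before any estimation the
traits are aligned to the primary (exposure) set's effect allele. Swapped
allele pairs flip the sign of beta and replace eaf by $1-\mathrm{eaf}$;
strand flips are resolved through base complements. Palindromic variants
(A/T, G/C) cannot be oriented from alleles alone: they are kept only when
every trait's aligned frequency is outside $0.5 \pm 0.08$ (configurable)
and all frequencies agree in orientation, otherwise dropped as
`palindromic_ambiguous`. This drop-if-ambiguous rule is an explicit design
choice — common upstream tooling instead infers orientation from
frequency — and every input variant is accounted for either in the
aligned arrays or in the drop report.

Instrument selection applies, in order: the significance threshold
($p < 10^{-5}$ for exposures, $p < 5\times10^{-8}$ in the reverse
direction), greedy LD clumping (smallest p first, ties broken
lexicographically by snp_id; discard neighbours within 10,000 kb with
$r^2 > 0.001$; variants absent from the LD matrix count as unlinked, with
a warning), then the weak-instrument filter. Explained variance is
computed per variant from the expanded formula
$R^2 = 2\beta^2 f(1-f) / (2\beta^2 f(1-f) + se^2\, 2 n f(1-f))$ — the
$2f(1-f)$ factor cancels algebraically, leaving
$\beta^2/(\beta^2 + se^2 n)$, but the expanded form is kept as the
definition — and $F = R^2(n-1-k)/((1-R^2)k)$ with $k=1$ per variant.
Exclusion is per variant and strict: a variant with $F$ exactly at the
bound is weak. The aggregate $F$ over survivors (summed $R^2$, $k$ = count,
$n$ = minimum sample size) is reported but not used for exclusion, because
excluding individual variants only makes sense per variant.

# The estimator battery

* **IVW**: weighted zero-intercept regression with weights
  $1/\sigma_{Yj}^2$. The fixed-effect SE is analytic; the multiplicative
  random-effects SE inflates it by $\max(1, \sqrt{Q/(k-1)})$ with $Q$
  Cochran's statistic. The primary `ivw` row uses the random-effects SE
  whenever $Q$ exceeds its degrees of freedom, since heterogeneity is the
  rule in practice; explicit fixed/random rows are available
  (`include_ivw_flavors`), and the default battery reports the four
  flavours primary / robust / penalized / penalized-robust.
* **Robust variants** use MM-estimation (Tukey bisquare, tuning constant
  4.685, S-estimate start) via `MASS::rlm`; on numerically exact data the
  closed-form fit is returned directly because the M scale step degenerates
  at zero residual scale.
* **Penalized variants** multiply each weight by $\min(1, 20 p_j)$ where
  $p_j$ is the upper-tail $\chi^2_1$ probability of the variant's
  heterogeneity contribution $Q_j = w_j(\hat\theta_j - \hat\theta)^2$ at
  the unpenalized fit, then refit; robust+penalized composes both.
* **MR-Egger** adds an intercept after orienting all exposure effects
  non-negative; the intercept estimates the mean directional-pleiotropy
  effect and its $t$-test ($k-2$ df) is the pleiotropy diagnostic
  ($p > 0.05$ read as no significant directional pleiotropy).
* **Maximum likelihood** profiles the per-variant nuisance means out of
  the bivariate normal likelihood, leaving a one-dimensional optimization
  of $-\tfrac12\sum (\hat\beta_{Yj}-\theta\hat\beta_{Xj})^2 /
  (\sigma_{Yj}^2 + \theta^2\sigma_{Xj}^2)$; the SE comes from the observed
  information (central second difference, step $10^{-5}(1+|\theta|)$).
* **Debiased IVW** subtracts the exposure sampling variance from the IVW
  denominator, $\hat\theta = \sum w_j\hat\beta_{Xj}\hat\beta_{Yj} /
  \sum w_j(\hat\beta_{Xj}^2 - \sigma_{Xj}^2)$, with a method-of-moments
  sandwich SE; it is consistent under many weak instruments, and a
  non-positive denominator raises a weak-instrument degeneracy error.
* **Contamination mixture** scores each candidate $\theta$ on a grid
  (2001 points over mean $\pm$ 6 SD of the ratios by default) by letting
  each variant choose the better of a valid component
  $N(\theta, se_j^2)$ and an invalid component $N(0, se_j^2+\psi^2)$;
  $\psi$ defaults to 1.5 times the SD of the ratio estimates. The 95%
  interval is the profile set within $\chi^2_1(0.95)/2$ of the maximum;
  its hull is reported with a multimodality flag, and an all-identical
  ratio set returns the common ratio with a degenerate-interval flag.
* **MR-Lasso** gives every variant a potential direct effect under an L1
  penalty; along a decreasing penalty path the chosen $\lambda$ is the
  largest whose selected valid subset has Cochran $Q$ below its
  $\chi^2$ 95th percentile, and the estimate is the post-selection
  fixed-effect IVW on that subset.
* **BWMR** is a deterministic variational EM for a Bayesian
  measurement-error model with a shared pleiotropy variance; between
  updates, variants are down-weighted by Tukey-bisquare weights on
  standardized posterior-predictive residuals. The weight rule is this
  package's explicit choice (the model family prescribes iterative
  re-weighting but not a specific weight function); it is smooth,
  redescending, and leaves clean data essentially unweighted.
* **cML** fits, for each candidate invalid count $K$, a constrained ML in
  which the $K$ largest residual contributors get free direct effects,
  scored by $\mathrm{BIC}(K) = 2\,\mathrm{nll} + K\log n_\mathrm{eff}$
  with $n_\mathrm{eff}$ the smallest GWAS sample size; `BIC` picks the
  argmin, `MA-BIC` model-averages with BIC weights. Data perturbation
  reruns the procedure on $\beta \pm se\cdot z$ resamples; the point
  estimate is always the unperturbed one and the reported SE is the
  across-perturbation spread floored at the analytic SE, so enabling
  perturbation can only widen uncertainty.
* **MR-PRESSO** compares the observed leave-one-out residual sum of
  squares (residuals standardized by $\sigma_{Yj}$) against parametric
  simulations that resample both effect columns; the per-variant outlier
  test is Bonferroni-adjusted, and the distortion test compares the
  outlier-removal shift against random removals of the same size. All of
  it is driven by an explicit seed.

`run_battery()` executes every configured method, records per-method
errors without aborting, and emits a deterministic row order. P-values
are two-sided normal for closed-form estimators and $t$ with $k-2$ df for
the Egger slope and intercept.

# The robustness verdict

The screening pipeline condenses a battery into a verdict: `robust`
requires the primary IVW $p < 0.05$ plus five checks — sign agreement of
every succeeding estimator, all Egger-intercept variants $p > 0.05$,
MR-PRESSO clean (or a corrected estimate that keeps the sign and stays
significant), all supplementary methods significant with the primary
sign, and a null reverse direction. This five-part conjunction is the
package's explicit codification of a "strong and robust" call; it is
deliberately a pure function of the battery outputs, so it is unit-tested
with hand-built tables, and each threshold is configurable. A reverse
analysis with no genome-wide-significant instruments counts as null by
convention and is flagged (`reverse_estimable = FALSE`) rather than
treated as disqualifying. The mediator scan reports BH-adjusted step-1
p-values alongside nominal ones for transparency, but the headline gate
stays nominal.

# The synthetic generator and what it does (not) show

`simulate_triad()` draws frequencies $f_j \sim U(0.1, 0.9)$, instrument
effects $\gamma_j \sim N(0.15, 0.05^2)$, and observes each trait's effects
with analytic noise $se = 1/\sqrt{2nf(1-f)}$ on a continuous standardized
scale. Default sample sizes mirror the motivating design: 5,959 for the
exposure GWAS, 3,757 for the mediator GWAS, 321,040 for the binary
outcome GWAS (whose effects are interpretable as log odds ratios; no
liability model is simulated because every estimator consumes only
(beta, se) pairs — a documented limitation). Variants sit 20 Mb apart on
cycling chromosomes so clumping is trivially satisfiable, the LD matrix
is the identity unless supplied, samples are non-overlapping by
construction, and everything is reproducible from the mandatory seed.
Pleiotropy can be balanced or directional with an affected fraction;
contamination plants random-sign direct effects of 5–10 times the
pleiotropy SD (or 0.05 when that SD is zero) so planted outliers are
unambiguous in fixtures.

One generative subtlety matters for mediation: if the mediator's only
genetic effects are $a\gamma_j$, the exposure and mediator effect columns
are collinear in expectation and the conditional effect $b$ is not
identified (conditional F near 1). Real mediator GWAS contribute their own
instruments; in this generator that channel is the mediator-side direct
effect term (whose $b\times$ image on the outcome is part of the causal
structure, not an exclusion-restriction violation). The mediation-recovery
study condition therefore adds a balanced mediator-specific component
(SD 0.15, affecting half the variants), which lifts the mediator's
conditional instrument strength well above the weak-instrument bound.

Passing tests on these simulations show estimator correctness and
calibration under the stated generative model; they do not certify
behaviour under realistic LD, case-control ascertainment, sample overlap,
or indel/multi-allelic variation, all of which are out of scope.

# Numerical choices and problem sizes

Simulation-backed checks use sizes chosen once for a desk-scale run:
fixed-effect IVW coverage over 500 replicates of 50 variants at
$n = 50{,}000$ per trait (coverage is checked against [0.92, 0.98]);
mediation recovery over 100 triads of 100 variants at the same $n$;
reverse-null type-I error over 500 replicates of 20 variants at the
default sample sizes; Egger-intercept recovery over 200 replicates with
directional pleiotropy mean 0.02. Convergence tolerances: $10^{-8}$ on
successive causal-effect updates for BWMR (max 500 iterations), $10^{-10}$
for the cML inner loop (converged on the objective so that tied
zero-residual variants cannot oscillate the invalid set), $10^{-10}$ for
the lasso coordinate updates. Degenerate inputs are first-class: exact
fits bypass the M-scale step of robust regression, an all-identical ratio
set short-circuits the contamination mixture, a zero total effect flags
the mediation proportion undefined instead of dividing by zero, and an
identically-zero exposure column in multivariable IVW is dropped from the
fit and reported as NA rather than crashing the solve.

# Known limitations

Ratio SEs use the first-order delta method (exposure uncertainty enters
only the estimators built for it); the multivariable conditional F ignores
cross-trait sampling covariance, which two-sample summary data do not
provide; the proportion-mediated CI treats the total effect as fixed by
default (the product term dominates; the full three-term delta variance is
available via `total_fixed = FALSE`); and no multiplicity correction is
applied to the mediation gates beyond the reported BH column, mirroring
the nominal two-step design.
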