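---
title: "Growth-curve trajectory modelling with trajlmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve trajectory modelling with trajlmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajlmm)
```

## The model

trajlmm fits multilevel (mixed-effects) growth-curve models to repeated
measures of a continuous outcome — symptom scores, height, BMI — observed at
varying ages or times within individuals. For subject $i$ at occasion $j$:

$$
y_{ij} \;=\; \sum_{d=0}^{D}\beta_d\, t_{ij}^{\,d} \;+\; x_{ij}'\gamma
\;+\; \sum_{d=0}^{q-1} u_{id}\, t_{ij}^{\,d} \;+\; \varepsilon_{ij},
\qquad u_i \sim N(0, G), \quad \varepsilon_{ij} \sim N(0, \sigma^2/w_{ij}),
$$

with a fixed polynomial in time of degree $D \in \{1,\dots,4\}$, subject-level
random intercept/linear/quadratic deviations ($q - 1 \in \{0, 1, 2\}$,
$q - 1 \le D$), optional covariates, optional precision (survey) weights
$w_{ij}$, and an optional *interaction variable* whose main effect and
products with every polynomial term give group-specific trajectories. Repeated
measures within a person are correlated; the random effects carry that
correlation, so standard errors are valid where an ordinary regression's would
not be.

Missing outcomes are handled by the likelihood itself: a subject simply
contributes fewer rows, which is valid whenever missingness does not depend on
the unobserved values (the recovery simulations below exercise the
missing-completely-at-random case). Rows with missing covariates are excluded
listwise, and rows with a missing time are kept in the long data but excluded
from fitting (the model needs a time; the rows still inform per-occasion
descriptives).

## Estimation

The deviance is profiled: writing $G = \sigma^2 \Lambda\Lambda'$ with
$\Lambda$ the lower-triangular *relative* Cholesky factor, both $\beta$
(generalised least squares) and $\sigma^2$ (a residual quadratic form) have
closed-form maximisers given $\Lambda$, leaving an optimisation over the
$q(q+1)/2$ free elements of $\Lambda$ only. The diagonal of $\Lambda$ is
parameterised on the log scale ("log-Cholesky"), so $G$ is positive
semidefinite by construction rather than by projection. Per-subject
quantities use the Woodbury identity on $q\times q$ matrices, implemented in
compiled code, so a 500-subject cubic fit takes on the order of a second.

Choices that matter:

* **Optimiser.** Quasi-Newton (`nlminb`/PORT) on the profiled deviance,
  relative tolerance `1e-8`, at most 500 iterations, followed by
  restart-from-solution polishing because PORT occasionally reports "singular
  convergence" slightly short of the optimum. `control = list(polish = TRUE)`
  adds damped Newton steps with central-difference derivatives for work that
  needs closed-form-level accuracy (the variance parameters are otherwise
  accurate only to roughly the square root of the objective tolerance).
  Non-convergence raises a structured error carrying the optimiser
  diagnostics rather than returning a silent wrong answer.
* **ML vs REML.** ML is the default (deviances comparable across nested fixed
  structures); REML uses the integrated-likelihood criterion
  $-2\,\ell_R = (n-p)\log(2\pi\sigma^2) + \sum_i \log|V^*_i| +
  \log|X'V^{-1}X|\,\sigma^{2p} + \mathrm{RSS}/\sigma^2$ (the same constant
  convention as the standard mixed-model implementations, against which the
  test suite cross-checks). REML deviances are flagged as non-comparable
  across different fixed-effects structures.
* **Time centring.** Raw-age polynomial bases up to degree 4 are badly
  conditioned (ages 3–20 give $t^4$ up to $1.6\times10^5$), so fitting always
  happens on $t - \bar t$. The estimates are then mapped back to the original
  time scale by the exact polynomial change of basis, block-by-block for
  interaction terms, and likewise for $G$. Every reported quantity is
  therefore *exactly* invariant to centring; the `time_center` argument only
  selects the basis on which `coef(fit, scale = "centered")` is displayed.
  Coefficient tables are reported on the original time scale, matching the
  formula the model prints.
* **Weights** are precision (inverse-variance) weights: the residual variance
  of a row is $\sigma^2 / w_{ij}$. This is the convention of the mainstream
  mixed-model fitters; survey weights supplied on this understanding scale
  each observation's information.
* **Encodings.** Categorical variables are treatment-coded with the *lowest*
  level as reference — numeric order when every level parses as a number,
  byte order otherwise; this silently determines the reference group, hence
  it is fixed and documented. Continuous interaction variables are
  standardised to mean 0, sd 1 (sample sd); numeric columns with at most two
  distinct values (e.g. 0/1 sex) are treated as categorical. All constants
  are recorded in the fit and reused verbatim when a model artifact is
  reloaded — never recomputed from new data.
* **Degenerate fits.** An exact-fit limit ($\mathrm{RSS}\to 0$) is kept
  finite by flooring $\hat\sigma^2$ at `1e-10` of the outcome's mean square;
  a random-effect eigenvalue below `1e-8 * max(trace(G), 1)` marks the fit
  `singular` with a warning, mirroring boundary-fit behaviour, but does not
  abort. Rank deficiency of the fixed design is a hard error naming the
  collinear columns rather than silent dropping.
* **Wald inference.** `fixed_effects()` reports $z = \hat\beta/\mathrm{se}$
  against the standard normal with the unrounded multiplier
  $\Phi^{-1}(0.975) = 1.959964\ldots$; no small-sample degrees-of-freedom
  correction is attempted, which is the convention of the surrounding
  ecosystem's summaries.

## Trajectory quantities

Every interpretable quantity is a linear contrast $c'\beta$ with exact
variance $c'Vc$, $V = \widehat{\mathrm{Var}}(\hat\beta)$:

* **Score at an age**: $c = (1, t, t^2, \dots)$ plus covariate entries at the
  display profile (continuous covariates at their fit-sample mean,
  categorical at reference — the same convention the coefficient display
  uses). Times outside the observed range are allowed with an extrapolation
  warning.
* **Area under the curve** over $[a, b]$: the fitted mean is polynomial, so
  the integral is itself a linear contrast — the column for $t^d$ gets weight
  $(b^{d+1} - a^{d+1})/(d+1)$, constant columns get their value times
  $(b-a)$. The AUC is computed analytically, not by quadrature (the two agree
  to $10^{-9}$ in the tests), and it is a *signed* integral: negative
  outcomes integrate negatively, consistent with the cumulative-exposure
  reading.
* **Group contrasts**: difference at an age and AUC difference are contrast
  differences between two interaction levels; all non-interaction covariate
  entries cancel, and the standard error uses the full covariance — not a
  combination of the two groupwise standard errors.

`boot_ci()` offers a seeded parametric bootstrap ($\beta^* \sim
N(\hat\beta, V)$, percentile interval) for users who distrust the normal
interval; it converges to the Wald interval as draws grow and is used as an
independent oracle in the test suite.

**Individual trajectories.** `subject_effects()` returns BLUPs — conditional
means $\hat u_i = G Z_i'(Z_i G Z_i' + \sigma^2 W_i^{-1})^{-1}(y_i -
X_i\hat\beta)$ at the plug-in parameter estimates. No uncertainty inflation
for having estimated $G$ and $\sigma^2$ is attempted; this matches standard
practice and is a known limitation (the reported individual curves are best
predictions, not intervals). Individual curves are drawn over each subject's
own observed time range by default, so individual-level extrapolation never
happens silently; `sample_individuals()` draws up to 30 reproducible curves
(R's Mersenne Twister, explicit seed recorded in the output attributes),
overall or within a group.

## The synthetic cohort generator

`sim_config()` defines the data-generating process used throughout the tests:
subject-level polynomial trajectories with correlated random
intercept/linear/quadratic deviations, per-occasion age jitter, Gaussian
residual noise, an optional binary group effect, and MCAR and/or monotone
dropout missingness. The defaults emulate a five-wave childhood/adolescence
cohort of parent-rated emotional-symptom scores: nominal ages 3, 5, 7, 11,
14; age jitter sd 0.25 years (real cohorts measure children at varying ages);
cubic mean trend $2.2 - 0.35t + 0.045t^2 - 0.0013t^3$ (a shallow dip through
mid-childhood rising into adolescence on a 0–10 scale); random-effect sds
(0.9, 0.10, 0.008) with correlations $-0.4$, $0.1$, $-0.5$; residual sd 0.7.
These values are the package's own choice of a realistic configuration — they
are fixed once, not tuned.

What the generator deliberately does *not* emulate: bounded/discrete score
scales (outcomes are Gaussian, so simulated scores can stray outside 0–10),
floor effects, informative (MNAR) dropout, cohort effects, or measurement
invariance problems across waves. Passing tests therefore demonstrate that
the *estimation machinery* is correct and calibrated under the stated model,
not that the model is adequate for any particular real cohort.

`recovery_study()` closes the loop: simulate → reshape → fit per replicate,
then bias, empirical SE, Monte-Carlo SE and CI coverage per parameter, with
non-converged replicates counted rather than fatal. The test suite runs 200
replicates at $n = 500$ subjects (the default configuration) and repeats the
exercise under 20% MCAR missingness; the acceptance script uses 60 replicates
at $n = 250$ to keep its runtime modest. Coverage is required to fall in the
binomial band $[92\%, 98\%]$ for a nominal 95% interval.

## Design decisions on open points

* Long rows whose outcome is missing are **kept** in the reshaped data (and
  dropped only at fit time): they still carry the occasion's age for
  descriptive summaries. Quartiles use linear interpolation between order
  statistics (R's default type-7 rule), fixed for test determinism.
* Occasion labels default to 1-based integers in column order.
* Duplicate subject identifiers in wide input are a validation issue, since
  wide format promises one row per individual.
* The long-format writer emits the literal `NA` for missing cells and the
  shortest decimal string that parses back to the identical double for reals,
  making the write/read cycle lossless.
* Model artifacts are versioned JSON with 17-significant-digit reals;
  contrasts rebuilt from an artifact are bit-identical to in-session ones.
* No hard cap is enforced on input size (upload limits are a hosted-app
  concern, not a library one).

## Known limitations

Gaussian outcomes only; nested (subject) random effects only — no crossed
designs, autocorrelated residuals, splines or fractional polynomials, and no
latent-class/mixture extensions; listwise deletion (not imputation) for
covariates; BLUPs without estimation-uncertainty inflation; Wald (normal)
p-values without small-sample df corrections.

## Worked example

```{r example}
cfg <- sim_config(n_subjects = 300, seed = 11)
cohort <- simulate_cohort(cfg)
sp <- wide_spec("subject", paste0("age_t", 1:5), paste0("y_t", 1:5),
                occasion_name = "occ", outcome_name = "sdq", age_name = "age")
long <- reshape_wide_to_long(cohort$data, sp)
describe_by_occasion(long, "sdq", "occ", "age")

fit <- trajlmm(long, outcome = "sdq", time = "age", subject = "subject",
               fixed_degree = 3, random_degree = 2)
summary(fit)

predict(fit, at = c(5, 10, 14))
traj_auc(fit, from = 3, to = 10)
```
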