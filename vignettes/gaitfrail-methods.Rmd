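---
title: "gaitfrail: methods, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gaitfrail: methods, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the model and its assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, the
numerical decisions taken where the design was genuinely open, and the
known limitations. It states no empirical result that the test suite
does not itself compute.

## 1. The estimation problem

A subject walks with in-shoe motion sensors recording nine channels at
100 Hz: accelerations $A_x, A_y, A_z$ (medial / posterior / superior
positive), angular velocities $G_x, G_y, G_z$ (plantarflexion /
eversion / internal-rotation positive) and sole-to-ground Euler angles
$E_x, E_y, E_z$. The target is the subject's hand grip strength (HGS,
kg), measured once per subject by dynamometer. Each subject
contributes `n_trials` walking trials; each trial is reduced to one
averaged, normalized stride (a $9 \times 100$ matrix over percent gait
cycle, %GC) plus 20 spatiotemporal gait parameters. Rows of the
analysis table are therefore *trial averages*, four per subject, and
every cross-validation step must respect the subject grouping.

## 2. Signal processing assumptions

* **Stride segmentation.** Heel strikes are prominent maxima of $A_z$
  (the landing spike) with a 0.4 s refractory period; toe offs are the
  upward zero crossing of $G_x$ immediately preceding the swing
  plantarflexion peak, searched after 25% of the stride. These are
  *operational simplifications* of the published event detectors the
  original pipeline cites; the synthetic generator provides
  ground-truth events, and the tests require detection within ±3
  samples. Real-data event detection would need the cited algorithms.
  A stance fraction outside (0.45, 0.75) raises a typed error rather
  than producing silently implausible strides — this is what rejects
  degenerate inputs such as time-reversed signals.
* **Temporal normalization.** Stance is linearly resampled to columns
  1–60, swing to 61–100. Linear interpolation was chosen as the
  simplest monotone scheme; the temporal split is driven entirely by
  the detected toe off.
* **Neutral-posture bias removal.** The per-channel mean over
  21–25 %GC (foot flat) is subtracted. Whether bias removal precedes
  or follows velocity normalization is not fixed by the source
  material; this package removes bias **first** (the order is fixed
  and tested). Velocity integration, however, uses the *raw* forward
  acceleration $-A_y$ from the neutral posture to the end of the
  stride (with $v(\text{neutral}) = 0$), because de-biased
  acceleration would integrate a constant-acceleration stride to zero.
* **Velocity normalization.** The six inertial channels are divided by
  the maximum instantaneous walking velocity $v_{max}$; Euler-angle
  channels are untouched. $v_{max} \le 0.05$ m/s is treated as a
  degenerate stride (error), not clamped.
* **Stride filtering.** The first and last three strides of a trial
  are always discarded. The outlier rule is stated as "> 3 SD from
  the trial mean" on duration and $v_{max}$, but with the small
  retained counts typical here a gross outlier dominates a mean/SD
  that includes it (with $n = 4$ the largest possible deviation is
  $1.5$ SD). The rule is therefore implemented **leave-one-out**: a
  stride is an outlier if it deviates from the mean of its peers by
  more than $\max(3\,\mathrm{SD}_{loo},\, 10\%)$. This reproduces the
  worked small-sample examples and is robust in noise-free worlds
  where the SD collapses to zero.
* **Double support (GP13/GP14).** True double-support times need the
  contralateral foot's events, whose published detectors are out of
  scope. Both are estimated as $\max(\text{stance} - T/2,\, 0)$ under
  a symmetric-gait assumption with the generator's fixed 60/40
  stance/swing split. They are place-holders with correct units, not
  validated gait measures.

## 3. The SPM stage and its thresholds

At each %GC node the squared canonical correlation $r^2$ between the
9-channel response and scalar HGS equals the $R^2$ of regressing HGS
on the nine channel values. The reported curve is the Bartlett–Wilks
statistic $X^2 = -(N - 6.5)\log(1 - r^2)$ with 9 nominal degrees of
freedom.

**Thresholding.** A canonical-correlation field with a *scalar*
target is exactly a Hotelling $T^2$ field with $p = 9$ components and
$\nu = N - 2$ error degrees of freedom, via
$T^2 = \nu\, r^2 / (1 - r^2)$. Thresholding the Bartlett statistic
with a $\chi^2_9$ random-field threshold is anticonservative at these
sample sizes: in the package's own null simulations the family-wise
error rate was about 0.21 at $N = 25$ (nominal 0.05) and still about
0.14 at $N = 100$. Two fixes were required, both kept:

1. The widely transcribed 1D Euler-characteristic density for
   $\chi^2$ fields is too small by a factor $\sqrt{2\pi}$. Deriving
   the density from the Rice upcrossing formula for
   $f(z) = \sum_i z_i^2$ of i.i.d. unit-variance smooth Gaussian
   fields gives
   $\rho_1(u) = \sqrt{4\log 2/\pi}\; u^{(k-1)/2} e^{-u/2} /
   (2^{(k-1)/2}\Gamma(k/2))$, which reduces at $k=1$ to twice the
   Gaussian density at $\sqrt u$ (the two-sided check) and was
   validated by Monte-Carlo upcrossing counts.
2. The CCA curve is thresholded as a $T^2$ field. The same Rice
   machinery applied to $f = \nu Z'W^{-1}Z$ ($Z \sim N_p(0,I)$,
   $W \sim \text{Wishart}_p(\nu, I)$, using the standard Wishart
   partition identities) yields the closed form
   $$\rho_1(u) = \sqrt{\tfrac{4\log2}{\pi}}\;
     \frac{\Gamma\!\big(\tfrac{\nu+1}{2}\big)}
          {\Gamma\!\big(\tfrac{p}{2}\big)
           \Gamma\!\big(\tfrac{\nu-p+2}{2}\big)}
     \Big(\tfrac{u}{\nu}\Big)^{(p-1)/2}
     \Big(1+\tfrac{u}{\nu}\Big)^{-(\nu-1)/2},$$
   which reduces to the two-sided $t_\nu$ density at $p = 1$ and to
   the corrected $\chi^2_p$ density as $\nu \to \infty$, and also
   matches Monte-Carlo upcrossing counts. The threshold is found on
   the $T^2$ scale and mapped through the monotone Bartlett transform,
   so the reported curve and its excursion set are unchanged in kind.
   After this correction the null family-wise rate in the acceptance
   suite sits inside $0.05 \pm 0.02$.

Field smoothness (FWHM, in %GC units) is estimated from the gradient
of the regression residual fields, pooled across channels for the CCA
curve and per channel for the post hoc curves, and clamped below at 1
node. The expected Euler characteristic used for the threshold is
$P(S > u) + \text{resels}\cdot\rho_1(u)$ with
$\text{resels} = 99/\text{FWHM}$, so the threshold falls to the
pointwise critical value as FWHM grows.

Post hoc Pearson SPM{t} curves are **two-sided** (both correlation
signs are biologically meaningful) at the Šidák level
$1-(1-\alpha)^{1/9}$; statistics are computed over the whole domain
but reported and thresholded only inside the CCA mask, which is the
conservative reading of "only significant nodes were further
investigated". A permutation-based max-statistic threshold is
implemented alongside purely as a test oracle, never on the default
path.

GPCs (maximal supra-threshold runs) are intersected with the fixed
quadriceps-activation windows $Q_t = \{1\text{–}16, 48\text{–}70,
92\text{–}100\}$ %GC; intervals are closed and a run spanning two
windows yields two predictors. The predictor value is the trapezoidal
integral average with unit step; a single-node interval returns the
node value (the degenerate branch), which makes both branches agree on
constant signals — the reading adopted for the typographically garbled
printed denominator.

## 4. LOSO-LASSO and model selection

The LASSO objective is $(1/2N)\sum_k (y_k - \beta_0 - x_k'\beta)^2 +
\lambda\|\beta\|_1$, solved by `glmnet` (the candidate predictors mix
years, cm, deg/s, so predictors are standardized inside each fit and
coefficients back-transformed; whether the original analysis
standardized is unstated, and this choice is recorded). Single-column
pools use the closed-form soft threshold. The λ path is a length-100
geometric sequence from the smallest all-zero λ down by a factor
$10^{-4}$ — the source fixes only "100 values, geometric", so the
bounds follow the standard convention and are exposed as arguments.

Each left-out subject's path supports form $B_u$; the stability
threshold on $B_0 = \sum_u B_u$ is $\lfloor 0.95\,U \rfloor$, i.e.
$B_0 \ge 25$ of 27 (males) and $\ge 33$ of 35 (females), the only
reading that reproduces both printed values. Candidate subsets
(columns of $B$) are deduplicated for evaluation but retain their
100-column accounting; ties in LOSOCV ICC(2,1) break toward fewer
predictors, then the smaller λ index (parsimony; unspecified in the
source). Cross-validated ICC treats (reference, prediction) rows as
two raters over all trial rows. Reported coefficients are refit on
all rows. Runs are sex-stratified throughout.

A property worth knowing when reading null results: selecting the
maximum-ICC candidate among ~100 induces a winner's-curse lift above
zero even with honest leave-one-subject-out folds, because chance
*subject-level* correlations survive the removal of any single
subject. The null tests therefore assert the mean over replicate
cohorts, not a single draw.

## 5. Agreement statistics

ICC(2,1)/ICC(2,k) come from the two-way ANOVA decomposition
(absolute agreement); the average-measures form equals the
Spearman–Brown transform of the single-measures form, an algebraic
identity the tests exploit as a cross-check oracle. Interpretation
bands use the published cut-points with boundary values assigned to
the interval that literally contains them.

Bland–Altman: differences are KS-tested for normality before the
parametric bias tests; limits of agreement are bias ± 1.96 SD. The
source names outer confidence limits (UULoA … LLLoA) without a
formula; the standard large-sample half-width
$1.96\,\sigma\sqrt{3/n}$ is used and documented as a substitution.

$K_A$ bounds: training residuals $R_A \sim N(0, \sigma_A^2)$, test
residuals $R_T \sim N(\mu_T, \sigma_T^2)$. $\sigma$ intervals use
$\chi^2_{n-1}$ pivots, $\mu_T$ a Student-$t$ interval (the source
states only "95% confidence levels"). The agreement interval is the
symmetric $\pm 1.96\,\sigma_{AU}$ of the *printed equations*; the
prose suggests $-1.96\,\sigma_{AL}$ as the lower bound, and the
printed form was followed (the equations also share identical bounds
between $K_{AU}$ and $K_{AL}$, differing only in max/min — implemented
exactly so). The (μ, σ) optimization is a 201 × 201 grid over the
confidence rectangle: the objective is smooth and 2-D, and the tests
hold the grid to a dense numeric-integration oracle within $10^{-3}$.
Masses are divided by the nominal inlier fraction 0.95 and clipped at
1 ("over 95% inside counts as 100%").

## 6. Frailty scoring

$Z$-scores use the population norms (HGS 34.7 ± 7.1 kg male,
21.9 ± 4.8 kg female; gait speed 1.29 ± 0.24 m/s, sex-pooled),
overridable via `population_norms()`. The printed integrals yield
values in [0, 1] while the prose constrains scores to 0–100; the
implementation multiplies by 100 and both scales are exposed
(`scale = "percent"`/`"unit"`), with the scale recorded on the output
— which also settles the open question of which scale downstream
figures used, by making it explicit. $P_{fr}$ is the equal-weight
mean. J-CHS scoring: one point per "yes" on the weight-loss and
exhaustion items, one point if both exercise items are "no", one
point below the sex-specific HGS cut-off (28/18 kg), one below
1.0 m/s; 0 → Robust, 1–2 → Pre-frail, ≥3 → Frail (">2" with integer
scores). The score is a population-percentile summary, not a
diagnostic probability.

## 7. The synthetic world

The generator is a first-class module, and its defaults are the
stated study conditions: 4 trials per subject, sex-specific HGS norms
as above, gait speed 1.29 ± 0.24 m/s, 16 strides per trial (≥ 10
required so that 6 lead-in/out strides can be discarded), stance/swing
fixed at 60/40 by construction, demographics drawn to match the
published cohort table means/SDs.

Channel templates are sums of a few periodic Gaussian bumps and low
harmonics — deliberately *not* biomechanically accurate, since
SPM/LASSO correctness does not depend on realism. Three features are
load-bearing and tested: $A_z$ has its dominant spike exactly at heel
strike; $G_x$ crosses zero upward exactly at 60% of the stride; $A_y$
is the negated derivative of a forward-velocity profile that is ~0 at
the neutral posture and integrates to the subject's gait speed, so
$v_{max}$, stride length and gait speed have closed-form truths.
Planted effects add `effect_size × (HGS − cohort mean)` to the
waveform inside chosen %GC windows, which must lie inside $Q_t$ so
recovery is possible after filtering. Noise is i.i.d. Gaussian per
sample smoothed by a 5-sample moving average, giving the residual
fields a non-degenerate smoothness (FWHM ≥ 3 %GC) so the RFT
assumptions are actually exercised; white noise would make them
degenerate. HGS is truncated at 0 kg (no truncation flag); gait
speed, heights and weights are truncated at physiological floors.

What the generator does **not** emulate — and therefore what a green
test does not establish: sensor error models and drift, the
orientation filter producing the Euler channels, turning or
non-steady gait, real between-subject waveform idiosyncrasy
(subject-level shape variation beyond the planted HGS effect),
correlated channel noise, and any biomechanical causal story. The
`duration_dist`/`stride_jitter_sd` fields exist so that noise-free
contracts (e.g. "zero noise ⇒ |r| = 1 for the planted predictor")
can freeze stride timing exactly.

The synthetic expert rater of the Test-2 analogue is declared, not
emulated: each of 6 raters scores `100 − true P_fr` plus rater bias
(SD 5) and noise (SD 10), clamped to 0–100. Its parameters live in
the run configuration.

## 8. Numerical conventions

* %GC columns are 1-based integers 1..100; intervals are closed.
* `glmnet` is run at `thresh = 1e-12` (single fits) so KKT conditions
  hold to ~1e-6; the acceptance suite checks coefficients against a
  sign-enumeration oracle at 1e-4.
* RFT thresholds are solved by `uniroot` at tolerance 1e-10 starting
  from the pointwise critical value (the root can only lie above it).
* Pathological smoothness estimates are clamped to [1 node, 10 ×
  domain]; rank-deficient response matrices fall back to a
  pseudo-inverse with a warning.
* ICC is undefined (typed error) only when *both* raters have zero
  variance; exact agreement of varying values returns 1.
* All randomness flows from one master seed split per stage;
  identical (spec, seed) reproduces cohorts bit-identically on disk
  (CSV values are written at fixed 6-decimal sensor quantization).

## 9. Known limitations

* Event detection and gait parameters GP05–GP07, GP13/14, GP19/20 are
  operational stand-ins validated only against the generator's truth.
* The headline numbers of the motivating study (ICC 0.978 for gait
  speed, MAE 2.88/2.57 kg, 16/8 selected predictors, r = −0.676)
  depend on unavailable human data and are not reproduction targets;
  the package's claims are the property-level ones its tests compute.
* The $T^2$ threshold controls the family-wise rate for the
  *vector-field* stage; the combined CCA→Pearson procedure is
  conservative by construction (post hoc tests are masked), not
  exactly calibrated.
* Trial averages of one subject share that subject's HGS; rows are
  not independent, which is why all resampling is by subject and why
  selection-stage ICCs must be read with the winner's-curse caveat of
  Section 4.
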