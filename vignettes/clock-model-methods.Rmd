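---
title: "Methods: the time-indexed clock model and its dysfunction metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the time-indexed clock model and its dysfunction metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotell)
```

# The model

`chronotell` treats the circadian clock as a noisy multigene dynamical
system. The joint distribution $P(t, g)$ of clock time $t$ and the
expression state $g$ of a small panel of rhythmic genes determines two
conditionals: $P(g\mid t)$, the scatter of clock states at a given
time, and $P(t\mid g)$, the information a single expression state
carries about the time. Since sampling times are (a priori) uniform
over the day, $P(t \mid g) \propto P(g \mid t)$ as a function of $t$,
so a model of $P(g\mid t)$ for all $t$ lets us score a single sample.

`clock_model()` estimates $P(g \mid t)$ from training timecourses as
follows.

1. **Normalisation.** Three modes: *timecourse* (each (instance, gene)
   training series to mean 0, SD 1, with the offsets and scales stored
   so test data from the same instances can be normalised identically —
   "timecourse-matched"), *intergene* (each sample vector standardised
   across its own entries, which maps a vector onto its shape and
   requires no recipe), and *both* (timecourse first, then intergene).
   Sample SD (divisor $n-1$) is used throughout. Timecourse-matched
   normalisation requires the test instance to appear in the training
   set and the same measurement platform; intergene works anywhere.

2. **Local projections.** At each training timepoint $t_i$ the $N_s$
   normalised panel vectors are centred and their first $d$ principal
   directions $U_d$ extracted. $d = 3$ by default: the residual scatter
   around the periodic attractor has rapidly decaying eigenvalues, so a
   3-dimensional projection captures the dominant gene–gene
   covariation while leaving enough samples per timepoint to fit a
   full-rank Gaussian. The projection applied to data is the linear map
   $U_d^\top g$ without centring; the centring shift is absorbed into
   the projected Gaussian means, which is an equivalent
   parameterisation and keeps evaluation a single matrix product.

3. **Per-timepoint Gaussians.** All timepoints' data are projected
   through each basis $U_d(i)$ and a Gaussian $N(\mu_j, \Sigma_j)$ is
   fitted per training time $j$ (sample mean, sample covariance). This
   "every timepoint through every basis" reading keeps each
   timepoint-indexed likelihood curve defined over the whole day; it is
   isolated in one place in the code so the alternative (each timepoint
   only through its own basis) could be swapped in.

4. **Periodic splines.** The $\mu_j$ (componentwise) and the
   $d(d+1)/2$ distinct entries of $\Sigma_j$ are interpolated over the
   day by a periodic monotone cubic Hermite (PCHIP) spline
   (`periodic_pchip()`): Fritsch–Carlson derivative limiting with
   wrap-around at the midnight seam, so every knot is interior, the
   interpolant is $C^1$ and 24-periodic, preserves monotone runs and
   reproduces constants. Covariances are splined entrywise — not by a
   log-Euclidean or other geometry-preserving scheme — because
   entrywise interpolation is the transparent choice and any loss of
   positive-definiteness between knots is detected and repaired (see
   below).

# Scoring a sample

For a normalised test vector $g$, each timepoint's likelihood curve is
the Gaussian log-density of $U_d(i)^\top g$ under the splined family,
evaluated on a dense grid (1440 points/day = 1-minute resolution by
default). The combined curve is the floored average

$$\log L_g(t) = \frac{1}{N_t}\sum_i \max\{\log L_{g,i}(t),\;
l_\mathrm{thresh}\},$$

which protects robust high local likelihoods from being wrecked by
inaccurate, exceptionally low ones. The internal phase $T$ is the grid
argmax (earliest grid time on ties, with `multimodal` / `flat_curve`
reported rather than hidden), $\mathrm{ML} = L_g(T)$, and the LRF is
$R_g(t) = L_g(t)/\mathrm{ML}$.

$\Theta$ is the fraction of grid times with
$R_g(t) > C(t\mid T) = \eta(1 + \varepsilon + \cos 2\pi(t - T)/24)$,
using a strict inequality so a curve exactly on the reference does not
count. The exceedance is always evaluated on the same grid as the
curve; at 1-minute resolution the discretisation error of $\Theta$ is
below $10^{-3}$.

**Parameters and defaults.**

| parameter | default | meaning |
|---|---|---|
| `d` | 3 | projection dimension; must be `< G` and `< N_s` |
| `lthresh` | −5 | log floor on per-timepoint curves (log-density units) |
| `eta`, `eps` | 0.35, 0.15 | reference curve $C$; must satisfy $0 < \eta\varepsilon < \eta(2+\varepsilon) < 1$ |
| `grid_n` | 1440 | grid points per day (1-minute steps) |

$\eta = 0.35, \varepsilon = 0.15$ give $\max C \approx 0.75$ and
$\min C \approx 0.05$: the main peak must occupy a reasonable fraction
of the likelihood mass before its width stops contributing to
$\Theta$, and truncated-flat regions only contribute once the maximum
likelihood is itself low. These defaults are held fixed across
datasets so $\Theta$ values are comparable; `lthresh`, in contrast, is
data-dependent and `choose_lthresh()` implements the selection rule:
take the largest floor such that (i) almost no training/control sample
has a truncated-flat LRF region rising above $C$ (default cap 5%), and
(ii) most test samples keep $\log \mathrm{ML}$ above the floor
(default 90%), with the full trade-off table returned for inspection.
Test MLs for rule (ii) are computed once at an essentially untruncated
reference floor; recomputing them per candidate would make the rule
circular.

The likelihood-ratio statistic $\lambda = \log(\mathrm{ML}/M)$ is also
reported, where $M$ is the model's own peak density at $T$ averaged
over timepoints on the same truncated-log scale; it is informative but
not thresholded by default.

**Dysfunction classification.** With the training score distributions
stored in the model: `lowML` below the 1% training quantile of
$\log \mathrm{ML}$; `highTvar` above the 99% training quantile of
$\Theta$ provided the excess is not purely a truncated-flat
contribution; `relTwrong` when a sample that is neither of the above
sits more than 4 h (circularly) from its known collection time. The
quantile defaults are deliberately conservative; they are parameters,
not constants.

# Numerical choices

- **Positive-definiteness repair.** Interpolated covariances are
  checked at every grid time (for $d=3$ via vectorised leading
  principal minors; otherwise per-point Cholesky) and repaired by
  eigenvalue clipping at $10^{-8}\,\mathrm{tr}(S)/d$ — deterministic,
  cheap, and logged in the model (`repairs_knots`, `repairs_grid`)
  rather than silent. Clipping is the first (and for covariance
  matrices the binding) step of the standard nearest-PD construction.
- **Degenerate covariances.** Sample covariances with condition number
  above $10^8$ (e.g. $N_s$ barely above $d$, or zero-noise fixtures)
  receive a ridge $10^{-6}\,\mathrm{tr}/d$ on the diagonal. On the
  dense grid, rows where cancellation destroys the adjugate-based
  inverse are recomputed through an eigendecomposition.
- **Reproducibility.** PCA component signs are fixed (largest-|loading|
  gene positive), so refitting the same data gives byte-identical
  model archives. The archive stores knot-level parameters only; the
  dense grid is rebuilt deterministically on load.
- **Circular arithmetic.** Times live in $[0, 24)$; signed errors in
  $(-12, 12]$ with $+12$ preferred at the antipode; displacements are
  circular means via the resultant vector and are declared undefined
  (not silently zero) when the resultant length drops below 0.1.
- **Phase unwrapping for regression.** Acrophases entering a
  phase-displacement regression are shifted by multiples of 24 h to
  the nearest representative around the gene's circular mean; genes
  whose unwrapped phases still span more than 6 h are flagged but
  reported, since the linear model presumes displacements are local.
- **Acrophase sign conventions.** `cosinor_fit()` returns the peak
  time (`acrophase`) and the classical cosinor `phase_lead`
  ($-\mathrm{acrophase}$ mod 24). A coherently shifted clock has
  *earlier* peaks and a *positive* timing displacement, so against
  displacement the peak time regresses with slope $-1$ and the phase
  lead with slope $+1$. Phase-displacement analyses here use
  `phase_lead`, the convention in which coherent shifts appear with
  unit positive slope.
- **Timestamp-free precision.** The window's expression vectors are
  projected on their first principal component; the mean of that
  summary over estimated time is smoothed with a Gaussian-kernel
  *local-linear* estimator (Silverman's rule bandwidth on the window's
  times). Local-linear rather than local-constant smoothing is used
  because the local-constant estimator carries first-order design bias
  at the window boundaries, which already breaks the noiseless linear
  case; the local-linear fit is exactly unbiased there. The smoothed
  curve is inverted through its monotone envelope (the curve must be
  essentially monotone — at most 20% wrong-sign slope — or the
  estimator refuses and suggests a narrower window).

# The synthetic cohort generator

`simulate_clock_data()` produces cohorts with exactly the statistical
structure the model assumes: per-gene cosinor means (amplitudes
0.6–1.4 log-units, mesors 6–10, acrophases evenly spread with ≤1 h
jitter — an even spread is what makes phase identifiable at all times),
an optional second harmonic (20% by default), per-instance chronotype
offsets applied coherently to all genes, optional per-(gene, instance)
incoherent offsets, and residual noise with a low-rank factor
structure (2 factors, loading SD 0.1) plus independent noise (SD
0.15). Offsets are defined as internal-clock *advances*: a $+\delta$
instance carries the expression state of time $t+\delta$, so its
estimated times run ahead of its collection times by $\delta$ and its
gene peaks come $\delta$ earlier.

`perturb_clock_data()` rebuilds a simulated cohort from the same noise
realisation with a perturbed mean structure — coherent or per-gene
phase shifts, amplitude collapse, single-gene knockout, or a frozen
clock pinned to one phase — so perturbation effects are exact
contrasts, not confounded with fresh noise.

**What passing tests do and do not show.** The generator draws
Gaussian noise around a smooth periodic attractor on a log-like scale;
it has no count-level noise, no batch or platform effects, no
missingness, and its residual covariance is time-constant. Tests on
these fixtures validate the estimator's correctness and its behaviour
under the perturbation archetypes; they do not certify performance on
real microarray/RNA-seq data, where panel choice, platform effects and
normalisation carry most of the practical risk.

The test-suite problem sizes — 12 genes × 6 timepoints × 12 instances
for the pinned cohort, 20 random model fits for the integrity checks,
100–400 Monte-Carlo iterations for the resampling checks — were chosen
so the whole suite exercises every code path at meaningful statistical
resolution while remaining quick to run routinely.

# Design decisions on genuinely open points

- **Rhythmicity ranking.** The panel-selection score combines the
  pooled cosinor rhythmicity p-value with the cross-instance acrophase
  dispersion (RMS circular deviation from the circular mean, in
  hours). It is a documented, generic ranking for "rhythmic and
  synchronous", not a reproduction of any particular published
  screen.
- **Order of "both" normalisation.** Timecourse first, then intergene:
  intergene normalisation of a timecourse-normalised vector is well
  defined, whereas the reverse would destroy the stored recipe
  semantics.
- **Leave-one-instance-out normalisation.** A held-out instance has no
  entry in the refit recipe, so its own timecourse provides its
  offsets and scales — the standard treatment of timecoursed test
  data. At the zero-noise limit this creates a small recipe asymmetry
  for leave-one-*sample*-out (the held-out sample's instance recipe is
  fitted on one fewer point than the others'), which is why the
  perfect-data validation runs under intergene normalisation.
- **Ellipsoid coverage.** Visualisation ellipsoids use Mahalanobis
  radius 3, which in 3 dimensions covers $\approx 97.1\%$
  ($\chi^2_3$); quoted coverages near 97.3% correspond to a slightly
  different convention and the discrepancy is accepted rather than
  hidden.
- **No confidence interval for `T`.** $\Theta$ is the exposed
  uncertainty statistic; a formal interval procedure would need the
  curvature machinery of the likelihood at its peak and is out of
  scope.

# Limitations

- Timecourse-matched normalisation restricts test data to instances
  (tissues/individuals) with a training timecourse on the same
  platform; intergene mode lifts the restriction at some cost in
  timing accuracy.
- The model assumes equal numbers of samples per training timepoint;
  leave-one-sample-out refits tolerate the imbalance with a warning,
  but heavily unbalanced designs dilute the per-timepoint Gaussians.
- With few training timepoints ($N_t = 6$ here) the splined family is
  only as good as PCHIP interpolation between knots; timing of states
  between knots is slightly less certain than at knots.
- The default differential-expression engine in the Θ-stratification
  is a per-gene rank-sum test with Benjamini–Hochberg adjustment — a
  deliberately simple, pluggable placeholder, not a substitute for a
  moderated-statistics DE package.
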