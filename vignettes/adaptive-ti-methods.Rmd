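---
title: "Adaptive resource allocation for thermodynamic integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive resource allocation for thermodynamic integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptiveTI)
```

## The problem

Alchemical thermodynamic integration (TI) estimates a free energy difference
by simulating a set of stratified equilibrium ensembles at fixed values of a
coupling parameter $\lambda \in [0,1]$ and integrating the mean Hamiltonian
derivative:

$$\Delta G_{A\to B} = \int_0^1 \left\langle \frac{dV}{d\lambda}
\right\rangle_\lambda d\lambda \;\approx\; \sum_{i=1}^{N} w_i \left\langle
\frac{dV}{d\lambda} \right\rangle_i ,$$

where $w_i$ are the integration weights of the chosen $\lambda$ schedule.
The dominant cost is molecular dynamics (MD) sampling, and how much sampling
each window needs is hard to predict a priori: some windows decorrelate in
picoseconds, others exhibit slow conformational exchange and converge only
after nanoseconds, if at all. Uniform per-window allocation therefore wastes
resources on easy windows and may underserve hard ones. This package
implements a per-window, data-driven stopping rule that allocates simulation
time on the fly, plus the estimation and evaluation stack around it.

## The stopping rule

Each $\lambda$ window is treated independently. After an initial production
block of `initial_length` ns, and after every extension of
`additional_length` ns, the accumulated raw gradient series is assessed:

1. **Automatic equilibration detection (AED).** Over a grid of candidate
   cuts $t_0$, the statistical inefficiency $g(t_0)$ of the retained tail is
   estimated and the cut maximizing the effective sample count
   $(N - t_0)/g(t_0)$ is chosen. This discards an initial transient exactly
   when doing so buys more usable data than it costs.
2. **Decorrelation.** The equilibrated tail is subsampled with stride
   $\lceil g \rceil$ (the statistical inefficiency rounded up to the nearest
   integer), yielding approximately independent samples.
3. **Convergence test.** The decorrelated series is split in half
   chronologically, each half binned into `n_bins` (default 7) equally
   spaced bins spanning the *pooled* range of both halves, and the
   Jensen–Shannon (JS) distance between the two histograms computed:
   $$\mathrm{JS}(P\|Q) = \sqrt{\tfrac12 D(P\|M) + \tfrac12 D(Q\|M)},
   \qquad M = \tfrac12 (P + Q),$$
   with base-2 Kullback–Leibler divergences $D$.
4. **Decision.** The window **converges** if JS $\le$ `js_threshold`
   (default 0.1) *and* at least `min_decorrelated` (default 50) decorrelated
   samples exist. Otherwise it stops at the **soft cap** (`soft_cap`,
   default 6.5 ns) provided *strictly more than* 50 decorrelated samples
   were collected, or unconditionally at the **hard cap** (`hard_cap`,
   default 10.5 ns); failing all of these, it **extends** by another block.

The named presets differ only in block sizes (initial/additional, ns):
A 2.5/0.5, B 1.5/0.5, C 1.0/0.25, D 0.5/0.25, E 3.5/0.5 with nine windows,
and C12 1.0/0.25 with twelve windows. All other knobs share the defaults
above; in particular E and C12 use the same 6.5/10.5 ns caps, since the caps
are defined once, independent of protocol.

### Statistical inefficiency

`statistical_inefficiency()` uses
$g = 1 + 2\sum_{\tau\ge 1} (1 - \tau/N)\hat\rho(\tau)$, truncating the sum
at the first non-positive $\hat\rho$ (the standard initial-positive-sequence
heuristic) and clipping to $g \ge 1$. The autocovariance is computed by FFT,
so a full AED grid search stays affordable. A constant (zero-variance)
series returns $g = 1$ with an explicit flag rather than an error, so the
controller can still count samples. For an AR(1) process the closed form is
$g = 1 + 2\phi/(1-\phi)$; the test suite checks recovery within 15% at
$N = 10^5$ for $\phi \in \{0.5, 0.9, 0.98\}$.

The AED candidate grid is every index when $N \le 1000$ and ~1000 evenly
spaced candidates over the first 90% of the series otherwise — a bounded-cost
approximation of the exact maximization, which the tests verify against an
exhaustive-grid oracle on short series.

### Numerical and convention choices

* **Logarithm base.** The JS divergence is computed in base 2, so the
  distance is bounded in $[0,1]$ and the 0.1 threshold sits on a normalized
  scale. This matters: with natural logarithms the same threshold would be
  effectively stricter by a factor of $\sqrt{\ln 2}$. The base is a
  deliberate, documented choice; the threshold remains a configuration knob.
* **Bin edges** come from the pooled min/max of both halves (not per-half),
  so the two probability vectors are directly comparable.
* **Ties.** JS exactly at the threshold counts as converged; the soft cap
  demands strictly *more than* the minimum sample count while convergence
  demands *at least* the minimum. The one-sample asymmetry is intentional
  and matches the rule as specified.
* **Sample counting.** The 50-sample requirement is applied to the full
  decorrelated series, before halving.
* **Degenerate assessments.** With fewer than two decorrelated samples the
  JS distance is undefined (reported as `NA`); such a window can only extend
  or, at 10.5 ns, stop at the hard cap — otherwise the controller could loop
  past the cap.
* **Cap checks occur only at assessment points**, so a run may first exceed
  a cap mid-block and stop at the next check; total time never overshoots
  the hard cap by more than one extension block.

## Estimation

Window means are gradient averages of the decorrelated series with bootstrap
standard errors (default 1000 seeded resamples; the resample count is a
package default, chosen as a common practice value). Two schedules are
provided: `gauss_legendre_schedule(n)` (weights sum to 1, exact to
polynomial degree $2n-1$) and `trapezoid_schedule(nodes)` for arbitrary
sorted nodes. A trapezoid schedule that does not span $[0,1]$ — such as the
nine equally spaced windows $0.1,\dots,0.9$ used for annihilation legs — is
flagged `truncated`: its weighted sum integrates only the covered range, and
endpoint treatment is deliberately left to the caller, since softcore
endpoint behaviour is engine-specific. Window errors propagate assuming
independent windows: $\mathrm{SE} = \sqrt{\sum_i w_i^2 s_i^2}$.

### Cycles

Relative binding free energies combine the protein-complex and water legs:
$\Delta\Delta G = \Delta G^{prot} - \Delta G^{wat}$. Absolute binding free
energies use the double-annihilation cycle with virtual-bond (Boresch-style)
restraints:

$$\Delta G^\circ_{bind} = \Delta G_{solv} - \Delta G_{+VB} -
\Delta G_{prot} - \Delta G^{\circ,analytic}_{-VB}.$$

The sign convention deserves a note: with four signed components there are
several superficially plausible orderings. The one above was adopted because
applying it to all six published component rows of the reference ABFE tables
backs out a *single* constant analytic restraint term (spread
$\le 0.03$ kcal/mol, value $\approx -7.50$ kcal/mol), and that value matches
the stiff-spring analytic formula evaluated at the reported restraint force
constants. The test suite performs both checks.

### Analytic restraint release

`boresch_analytic()` implements the stiff-spring closed form for releasing
one distance, two angle and three dihedral harmonic restraints
($U = \tfrac{k}{2}x^2$) into the standard-state volume
$V^\circ = 1660.5392\ \text{Å}^3$:

$$\Delta G = -RT \ln\!\left[\frac{8\pi^2 V^\circ\sqrt{k_r k_{\theta A}
k_{\theta B} k_{\phi A} k_{\phi B} k_{\phi C}}}{r_0^2 \sin\theta_A
\sin\theta_B (2\pi RT)^3}\right].$$

No symmetry-number terms are included. The tests validate the formula
against a numerical configurational integral (one-dimensional quadratures of
the separable six-dimensional restrained partition function) to within
0.05 kcal/mol in the stiff regime.

Constants are fixed at $R = 1.98720425864083\times 10^{-3}$ kcal/(mol K)
and default $T = 300$ K; all internal times are ns and energies kcal/mol,
with conversions only at I/O boundaries.

## The synthetic gradient backend

`make_sampler()` produces seeded streams implementing the sampler contract
used by the controller (`extend(duration)` appends contiguous samples). Five
stream kinds emulate behaviours real gradient series exhibit:

* `iid_gaussian` — a well-behaved, rapidly decorrelating window;
* `ar1` — long autocorrelation (stationary AR(1); statistical inefficiency
  $1 + 2\phi/(1-\phi)$), the regime where decorrelated samples stay scarce;
* `transient` — an unequilibrated start (exponentially decaying offset);
* `heteroscedastic` — spread doubling every fixed interval, a persistently
  non-converging stream;
* `two_state` — slow conformational exchange (mean switching).

Generation is counter-based: sample $i$ depends only on the stream seed and
$i$, never on how `extend()` calls were partitioned. This partition
invariance is what makes controller runs reproducible across protocols with
different block sizes, and is property-tested. The default cadence is one
sample per ps (`sampling_interval = 0.001` ns), a plausible gradient-output
frequency; it is always explicit in the spec.

**What the generator does not emulate:** fat-tailed gradient distributions
near softcore endpoints, multimodal conformational substates with realistic
exchange kinetics, or any coupling between windows. Passing tests on these
streams demonstrate that the stopping logic, estimators and bookkeeping are
correct — not that the 0.1 threshold or 50-sample minimum are well
calibrated for any particular molecular system.

## Evaluation statistics

`error_metrics()` reports MAE, RMSE and $R^2$. $R^2$ is defined as the
squared Pearson correlation of predicted versus reference values (not the
coefficient of determination about the identity line — with systematic
offsets the two differ; the choice is documented here because either reading
is defensible). `permutation_test()` reports the fraction of
label-permutation null metrics below the observed value, leaving one-sided
interpretation to the caller. `batch_resample()` draws replicate batches
without replacement within each transformation (independently across
transformations), averages, and recomputes the metrics; when only a single
combination exists the result is deterministic. `truncation_analysis()`
re-runs the equilibrate–decorrelate–average–integrate pipeline on gradients
truncated at each grid time, clamping to the available data.
`savings()` is the complement of the simulated-to-baseline time ratio;
time-step cost multipliers (e.g. doubling a 1 fs baseline) are deliberately
caller-supplied, not inferred.

## Problem sizes used in the tests

The suite exercises the controller at its natural scale: windows of
$10^2$–$10^4$ samples, statistical-inefficiency recovery at $10^5$ samples,
full-grid AED oracles on series up to 2000 samples, 200–2000 Monte Carlo
resamples for the distributional checks, and 9–12-window transformations.
These sizes make every oracle comparison exact or tightly bounded while the
whole suite runs in about a minute on one CPU.

## Known limitations

* BAR/MBAR estimators are out of scope (the stopping rule is compatible
  with them, but only TI integration is implemented).
* No replica-exchange or Hamiltonian-exchange fallback for windows that hit
  the hard cap unconverged; such windows are reported with their distinct
  stop reason and left to the user.
* The equilibration detector recomputes on the full accumulated series at
  every assessment (the simplest faithful reading of the loop); no
  incremental update is attempted.
* $\lambda$-schedule optimization is not addressed; schedules are inputs.
* The AMBER reader extracts instantaneous `DV/DL` records only; full energy
  decomposition parsing and other engines' formats are out of scope.
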