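# adaptiveTI

Adaptive, per-window resource allocation for alchemical **thermodynamic
integration (TI)** free energy calculations, plus the estimation and
evaluation stack around it — testable end to end without a molecular
dynamics engine.

## The problem

TI estimates a binding (or solvation) free energy by simulating stratified
ensembles at fixed values of the coupling parameter λ and integrating the
mean Hamiltonian derivative:

    ΔG = ∫₀¹ ⟨dV/dλ⟩_λ dλ  ≈  Σᵢ wᵢ ⟨dV/dλ⟩ᵢ

The expensive part is MD sampling, and the amount each λ window needs varies
wildly and unpredictably. This package implements a data-driven stopping
rule applied independently to every window's dV/dλ gradient time series:

1. **Automatic equilibration detection** — choose the cut t₀ that maximizes
   the effective sample count (N − t₀)/g(t₀), where g is the statistical
   inefficiency (1 + twice the integrated autocorrelation).
2. **Decorrelation** — subsample with stride ⌈g⌉.
3. **Jensen–Shannon convergence test** — split the decorrelated series in
   half chronologically, bin each half into 7 equally spaced bins over the
   pooled range, and compute the (base-2) JS distance between the two
   histograms.
4. **Decision** — converged if JS ≤ 0.1 with ≥ 50 decorrelated samples;
   otherwise stop at the 6.5 ns soft cap (if > 50 decorrelated samples) or
   the 10.5 ns hard cap; otherwise extend by a fixed block and reassess.

Around the controller: Gauss–Legendre and trapezoid λ schedules, bootstrap
gradient averaging, relative (ΔΔG = ΔG_prot − ΔG_wat) and absolute
(double-annihilation with Boresch-style virtual-bond restraints) cycle
assembly including the analytic standard-state restraint release term, an
AMBER `DV/DL` / CSV reader, and replicate-level evaluation statistics
(MAE/RMSE/R², permutation tests, batch resampling, truncation analysis,
computational-savings accounting). A seeded, partition-invariant synthetic
gradient generator stands in for the MD engine.

Audience: practitioners running alchemical free energy campaigns (RBFE lead
optimization, ABFE screening) and method developers studying adaptive
stopping rules for stratified time series.

## Worked example

Run a nine-window transformation against synthetic well-behaved windows
whose gradient means follow 3λ² (so the exact integral is 1):

```r
library(adaptiveTI)

sched <- gauss_legendre_schedule(9)
samplers <- lapply(seq_len(9), function(i)
  make_sampler(generator_spec("iid_gaussian", mean = 3 * sched$lambdas[i]^2,
                              sigma = 0.3, seed = 100 + i)))
out <- run_transformation(samplers, protocol_preset("A"), sched, boot_seed = 42)
print(out$result)
#> <free_energy_result> dG = 1.0032 +/- 0.0025 kcal/mol (gaussian_quadrature, 9 windows)
sum(sapply(out$records, `[[`, "total_time"))
#> [1] 22.5
savings(22.5, 90)   # vs a uniform 10 ns/window baseline
#> [1] 0.75
```

Every window converges at the first 2.5 ns check (white noise passes the JS
test easily), the 9-point quadrature integrates the degree-2 mean function
exactly, and the adaptive run uses a quarter of the uniform budget. A hard
window behaves differently — a strongly autocorrelated stream never
accumulates 50 decorrelated samples and runs to the hard cap:

```r
rec <- run_window(make_sampler(generator_spec("ar1", phi = 0.98,
                                sampling_interval = 0.01, seed = 7)),
                  protocol_preset("C"))
print(rec)
#> <window_run_record> lambda = 0, protocol C: 39 assessment(s), 10.5 ns -> hard_cap (final JS 1.0000, 9 decorrelated)
```

Absolute binding cycle with the analytic restraint release term:

```r
p <- boresch_parameters(r0 = 5, theta_A = pi/2, theta_B = pi/2,
                        k_r = 10, k_thetaA = 10, k_thetaB = 10,
                        k_phiA = 20, k_phiB = 20, k_phiC = 20)
boresch_analytic(p)
#> [1] -7.482122
abfe_assemble(17.32, 2.02, 31.02, boresch_analytic(p))$dg_bind
#> [1] -8.237878
```

A thin command-line front end is installed at `exec/adaptiveTI` with verbs
`schedule`, `simulate-gradients`, `assess`, `control`, `estimate`,
`evaluate` (see `exec/adaptiveTI` with no arguments for usage).

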