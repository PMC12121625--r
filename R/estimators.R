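#' Lambda schedule with integration weights
#'
#' A set of lambda nodes in \[0, 1\] together with the quadrature weights that
#' turn per-window gradient means into a free energy difference,
#' \eqn{\Delta G \approx \sum_i w_i \langle dV/d\lambda \rangle_i}.
#'
#' @param lambdas Sorted nodes in \[0, 1\].
#' @param weights Integration weights, same length.
#' @param rule `"gaussian_quadrature"` or `"trapezoid"`.
#' @param truncated Logical: does the schedule cover less than the full
#'   \[0, 1\] domain (so the weighted sum integrates only the covered range)?
#' @return An object of class `lambda_schedule`.
#' @seealso [gauss_legendre_schedule()], [trapezoid_schedule()]
#' @export
lambda_schedule <- function(lambdas, weights,
                            rule = c("gaussian_quadrature", "trapezoid"),
                            truncated = FALSE) {
  rule <- match.arg(rule)
  lambdas <- as.numeric(lambdas); weights <- as.numeric(weights)
  if (length(lambdas) != length(weights)) {
    stop("lambdas and weights must have equal length", call. = FALSE)
  }
  if (is.unsorted(lambdas, strictly = TRUE)) {
    stop("lambdas must be strictly increasing", call. = FALSE)
  }
  if (any(lambdas < 0 | lambdas > 1)) {
    stop("lambdas must lie in [0, 1]", call. = FALSE)
  }
  if (rule == "gaussian_quadrature") {
    if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-12) {
      stop("gaussian quadrature weights must be positive and sum to 1",
           call. = FALSE)
    }
  }
  structure(list(lambdas = lambdas, weights = weights, rule = rule,
                 truncated = isTRUE(truncated)),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("<lambda_schedule> %s, %d nodes%s\n", x$rule, length(x$lambdas),
              if (x$truncated) " (truncated domain)" else ""))
  cat("  lambdas:", paste(format(x$lambdas, digits = 5), collapse = " "), "\n")
  cat("  weights:", paste(format(x$weights, digits = 5), collapse = " "), "\n")
  invisible(x)
}

#' Gauss-Legendre lambda schedule on the unit interval
#'
#' Nodes and weights of the n-point Gauss-Legendre rule mapped affinely from
#' \[-1, 1\] to \[0, 1\]; the weights sum to 1 and the rule integrates
#' polynomials up to degree 2n - 1 exactly.
#'
#' @param n Number of nodes, >= 1.
#' @return A [lambda_schedule()] with rule `"gaussian_quadrature"`.
#' @examples
#' round(gauss_legendre_schedule(9)$lambdas, 5)
#' @export
gauss_legendre_schedule <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  gl <- pracma::gaussLegendre(as.integer(n), 0, 1)
  ord <- order(gl$x)
  lambda_schedule(gl$x[ord], gl$w[ord], rule = "gaussian_quadrature")
}

#' Composite trapezoid lambda schedule
#'
#' Composite trapezoid-rule weights for arbitrary sorted nodes in \[0, 1\].
#' A schedule that does not span the full unit interval (for example the nine
#' equally spaced windows 0.1, 0.2, ..., 0.9) is flagged as truncated: its
#' weighted sum integrates only over the covered range and endpoint handling
#' is left to the caller.
#'
#' @param lambdas Strictly increasing nodes in \[0, 1\], length >= 2.
#' @return A [lambda_schedule()] with rule `"trapezoid"`.
#' @examples
#' trapezoid_schedule(c(0, 0.05, 0.1, 0.2, 0.3, 0.5, 1))$weights
#' @export
trapezoid_schedule <- function(lambdas) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (anyDuplicated(lambdas) || is.unsorted(lambdas, strictly = TRUE)) {
    stop("nodes must be strictly increasing with no duplicates", call. = FALSE)
  }
  if (any(lambdas < 0 | lambdas > 1)) {
    stop("nodes must lie in [0, 1]", call. = FALSE)
  }
  d <- diff(lambdas)
  w <- c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  truncated <- !(isTRUE(all.equal(lambdas[1], 0)) &&
                 isTRUE(all.equal(lambdas[length(lambdas)], 1)))
  lambda_schedule(lambdas, w, rule = "trapezoid", truncated = truncated)
}

#' Bootstrap mean and standard error
#'
#' The gradient average of a decorrelated series with its bootstrap standard
#' error: `n_boot` resamples with replacement of the same size as the data;
#' the standard error is the standard deviation of the resampled means.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Number of bootstrap resamples, >= 100. Default 1000.
#' @param seed Integer seed for the resampling. Default 1.
#' @return A list with `mean` and `std_err`.
#' @export
bootstrap_mean <- function(values, n_boot = 1000, seed = 1) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  boot_means <- vapply(seq_len(n_boot), function(i) {
    mean(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  list(mean = mean(values), std_err = stats::sd(boot_means))
}

#' Integrate window gradient means into a free energy difference
#'
#' Computes \eqn{\Delta G = \sum_i w_i m_i} from per-window gradient means
#' \eqn{m_i} and the schedule weights, with the standard error propagated
#' assuming independent windows:
#' \eqn{\mathrm{SE} = \sqrt{\sum_i w_i^2 s_i^2}}.
#'
#' @param schedule A [lambda_schedule()].
#' @param window_means Per-node gradient means, kcal/mol.
#' @param window_errs Per-node standard errors, kcal/mol. Default 0.
#' @return An object of class `free_energy_result` with `delta_g`,
#'   `std_err`, `window_means`, `window_errs` and `rule`.
#' @export
ti_integrate <- function(schedule, window_means, window_errs = 0) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  window_means <- as.numeric(window_means)
  window_errs <- rep_len(as.numeric(window_errs), length(window_means))
  if (length(window_means) != length(schedule$lambdas)) {
    stop("window_means length must match the schedule", call. = FALSE)
  }
  if (any(window_errs < 0)) stop("window_errs must be >= 0", call. = FALSE)
  structure(
    list(
      delta_g = sum(schedule$weights * window_means),
      std_err = sqrt(sum(schedule$weights^2 * window_errs^2)),
      window_means = window_means,
      window_errs = window_errs,
      rule = schedule$rule,
      lambdas = schedule$lambdas,
      truncated = schedule$truncated
    ),
    class = "free_energy_result"
  )
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("<free_energy_result> dG = %.4f +/- %.4f kcal/mol (%s, %d windows%s)\n",
              x$delta_g, x$std_err, x$rule, length(x$window_means),
              if (x$truncated) ", truncated domain" else ""))
  invisible(x)
}

#' Assemble a relative binding free energy cycle
#'
#' \eqn{\Delta\Delta G_{bind}^{A\to B} =
#'   \Delta G_{A\to B}^{prot} - \Delta G_{A\to B}^{wat}}:
#' the difference between the alchemical A-to-B transformation in the
#' protein complex and in water.
#'
#' @param dg_prot Transformation free energy in the complex, kcal/mol.
#' @param dg_wat Transformation free energy in water, kcal/mol.
#' @return An object of class `rbfe_cycle` with `dg_prot`, `dg_wat`, `ddg`.
#' @examples
#' rbfe_assemble(3.87, 4.91)$ddg   # -1.04
#' @export
rbfe_assemble <- function(dg_prot, dg_wat) {
  if (!is.finite(dg_prot) || !is.finite(dg_wat)) {
    stop("inputs must be finite", call. = FALSE)
  }
  structure(list(dg_prot = dg_prot, dg_wat = dg_wat,
                 ddg = dg_prot - dg_wat),
            class = "rbfe_cycle")
}

#' Assemble an absolute binding free energy cycle
#'
#' Combines the three alchemical legs of the double-annihilation cycle with
#' Boresch-style virtual-bond restraints:
#' \deqn{\Delta G_{bind}^\circ = \Delta G_{solv} - \Delta G_{+VB}
#'   - \Delta G_{prot} - \Delta G_{-VB}^{\circ,analytic},}
#' where `dg_int_solv` annihilates the ligand in water, `dg_vb_add` adds the
#' virtual-bond restraints to the bound ligand, `dg_int_prot` annihilates the
#' restrained ligand in the complex, and `dg_vb_remove_analytic` is the
#' analytic free energy of releasing the restrained non-interacting ligand
#' into the standard-state volume ([boresch_analytic()]).
#'
#' @param dg_int_solv,dg_vb_add,dg_int_prot,dg_vb_remove_analytic The four
#'   cycle components, kcal/mol.
#' @return An object of class `abfe_cycle` with the components and `dg_bind`.
#' @examples
#' abfe_assemble(17.32, 2.02, 31.02, -7.51)$dg_bind  # -8.21
#' @export
abfe_assemble <- function(dg_int_solv, dg_vb_add, dg_int_prot,
                          dg_vb_remove_analytic) {
  vals <- c(dg_int_solv, dg_vb_add, dg_int_prot, dg_vb_remove_analytic)
  if (any(!is.finite(vals))) stop("inputs must be finite", call. = FALSE)
  structure(
    list(dg_int_solv = dg_int_solv, dg_vb_add = dg_vb_add,
         dg_int_prot = dg_int_prot,
         dg_vb_remove_analytic = dg_vb_remove_analytic,
         dg_bind = dg_int_solv - dg_vb_add - dg_int_prot -
           dg_vb_remove_analytic),
    class = "abfe_cycle"
  )
}

#' Boresch restraint parameter set
#'
#' Geometry and force constants of the six-dimensional virtual-bond
#' restraint (one distance, two angles, three dihedrals) anchoring a ligand
#' to its receptor. Harmonic energies follow the `k/2 * x^2` convention.
#'
#' @param r0 Reference anchor distance, Angstrom.
#' @param theta_A,theta_B Reference angles, radians, in (0, pi).
#' @param k_r Distance force constant, kcal/(mol A^2).
#' @param k_thetaA,k_thetaB Angle force constants, kcal/(mol rad^2).
#' @param k_phiA,k_phiB,k_phiC Dihedral force constants, kcal/(mol rad^2).
#' @param tc A [thermo_constants()] object.
#' @return An object of class `boresch_parameters`.
#' @export
boresch_parameters <- function(r0, theta_A, theta_B, k_r,
                               k_thetaA, k_thetaB, k_phiA, k_phiB, k_phiC,
                               tc = thermo_constants()) {
  ks <- c(k_r, k_thetaA, k_thetaB, k_phiA, k_phiB, k_phiC)
  if (!is.finite(r0) || r0 <= 0) stop("r0 must be > 0", call. = FALSE)
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("all force constants must be > 0", call. = FALSE)
  }
  for (th in c(theta_A, theta_B)) {
    if (!is.finite(th) || th <= 0 || th >= pi) {
      stop("angles must lie strictly inside (0, pi) radians", call. = FALSE)
    }
  }
  structure(list(r0 = r0, theta_A = theta_A, theta_B = theta_B,
                 k_r = k_r, k_thetaA = k_thetaA, k_thetaB = k_thetaB,
                 k_phiA = k_phiA, k_phiB = k_phiB, k_phiC = k_phiC,
                 tc = tc),
            class = "boresch_parameters")
}

#' Analytic restraint release free energy
#'
#' The free energy of removing the six harmonic virtual-bond restraints from
#' a non-interacting ligand and releasing it into the standard-state volume,
#' in the stiff-spring (Gaussian) limit:
#' \deqn{\Delta G = -RT \ln\!\left[\frac{8\pi^2 V^\circ
#'   \sqrt{k_r k_{\theta A} k_{\theta B} k_{\phi A} k_{\phi B} k_{\phi C}}}
#'   {r_0^2 \sin\theta_A \sin\theta_B\, (2\pi R T)^3}\right].}
#' For typical stiff restraints the result is negative: releasing the ligand
#' is favourable. Used as `dg_vb_remove_analytic` in [abfe_assemble()].
#'
#' @param p A [boresch_parameters()] object.
#' @return Free energy in kcal/mol.
#' @examples
#' p <- boresch_parameters(5, pi/2, pi/2, 10, 10, 10, 20, 20, 20)
#' boresch_analytic(p)  # about -7.5 kcal/mol at 300 K
#' @export
boresch_analytic <- function(p) {
  stopifnot(inherits(p, "boresch_parameters"))
  RT <- p$tc$R * p$tc$T
  sA <- sin(p$theta_A); sB <- sin(p$theta_B)
  if (sA <= 0 || sB <= 0) stop("sin(theta) must be positive", call. = FALSE)
  kprod <- p$k_r * p$k_thetaA * p$k_thetaB * p$k_phiA * p$k_phiB * p$k_phiC
  arg <- 8 * pi^2 * p$tc$V_std * sqrt(kprod) /
    (p$r0^2 * sA * sB * (2 * pi * RT)^3)
  -RT * log(arg)
}
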