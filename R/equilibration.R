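#' Statistical inefficiency of a time series
#'
#' Estimates the statistical inefficiency
#' \deqn{g = 1 + 2 \sum_{\tau \ge 1} (1 - \tau/N)\, \hat\rho(\tau),}
#' where \eqn{\hat\rho} is the normalized autocovariance function. The sum is
#' truncated at the first non-positive \eqn{\hat\rho} (initial-positive-sequence
#' heuristic) and the result is clipped to be at least 1. `ceiling(g)` is the
#' subsampling stride that yields approximately independent samples.
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @return A single number >= 1. For a zero-variance (constant) series the
#'   convention g = 1 is returned with attribute `zero_variance = TRUE`.
#' @examples
#' statistical_inefficiency(rnorm(1000))      # ~1 for white noise
#' @export
statistical_inefficiency <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  xc <- values - mean(values)
  c0 <- sum(xc^2) / n
  if (c0 == 0) {
    g <- 1
    attr(g, "zero_variance") <- TRUE
    return(g)
  }
  rho <- .autocorr_fft(xc, c0)
  # truncate at the first non-positive autocorrelation
  cut <- which(rho <= 0)
  keep <- if (length(cut)) cut[1L] - 1L else length(rho)
  g <- 1
  if (keep > 0L) {
    tau <- seq_len(keep)
    g <- 1 + 2 * sum((1 - tau / n) * rho[tau])
  }
  max(g, 1)
}

# Full normalized autocovariance (lags 1..N-1) of a centred series via FFT.
.autocorr_fft <- function(xc, c0) {
  n <- length(xc)
  m <- stats::nextn(2L * n, 2L)
  f <- stats::fft(c(xc, rep(0, m - n)))
  acov <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m / n
  acov[-1L] / c0
}

#' Automatic equilibration detection
#'
#' Finds the equilibration cut that maximizes the number of effectively
#' uncorrelated samples in the remaining series: over a grid of candidate
#' start indices \eqn{t_0}, the retained tail of length \eqn{N - t_0} with
#' statistical inefficiency \eqn{g(t_0)} yields
#' \eqn{N_{eff}(t_0) = (N - t_0) / g(t_0)}; the cut maximizing this is
#' selected. Decorrelated sample indices then start at the cut and step by
#' `ceiling(g)`.
#'
#' All indices in the result are 1-based (R convention): `t0_index = 1`
#' means no samples are discarded.
#'
#' @param series A [gradient_series()] (or bare numeric vector) of length >= 4.
#' @return An object of class `equilibration_result` with fields `t0_index`
#'   (1-based first retained sample), `g` (statistical inefficiency of the
#'   retained tail), `n_effective`, `decorrelated_indices` (1-based, stride
#'   `ceiling(g)`), and `zero_variance` flag.
#' @examples
#' gs <- gradient_series(c(rnorm(200, 10), rnorm(800)), 0.001, 0.5)
#' detect_equilibration(gs)$t0_index  # excludes most of the transient
#' @export
detect_equilibration <- function(series) {
  values <- if (inherits(series, "gradient_series")) series$values else as.numeric(series)
  n <- length(values)
  if (n < 4L) stop("need at least 4 samples for equilibration detection", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)

  # Degenerate: flat tail from the start.
  if (stats::var(values) == 0) {
    return(.equilibration_result(t0 = 1L, g = 1, n = n, zero_variance = TRUE))
  }

  # Candidate grid: every cut when the series is short; otherwise ~1000
  # evenly spaced cuts over the first 90% of the series.
  max_t0 <- n - 4L                       # leave at least 4 samples
  if (n <= 1000L) {
    cand <- 0:max_t0
  } else {
    cand <- unique(round(seq(0, min(floor(0.9 * n), max_t0), length.out = 1000L)))
  }

  best <- list(neff = -Inf, t0 = 0L, g = 1)
  for (t0 in cand) {
    tail_vals <- values[(t0 + 1L):n]
    g <- statistical_inefficiency(tail_vals)
    if (isTRUE(attr(g, "zero_variance"))) g <- 1
    neff <- (n - t0) / g
    if (neff > best$neff) best <- list(neff = neff, t0 = t0, g = as.numeric(g))
  }
  .equilibration_result(t0 = best$t0 + 1L, g = best$g, n = n,
                        zero_variance = FALSE)
}

.equilibration_result <- function(t0, g, n, zero_variance) {
  stride <- as.integer(ceiling(g))
  idx <- seq.int(t0, n, by = stride)
  structure(
    list(
      t0_index = as.integer(t0),
      g = as.numeric(g),
      n_effective = (n - t0 + 1L) / g,
      decorrelated_indices = as.integer(idx),
      zero_variance = isTRUE(zero_variance)
    ),
    class = "equilibration_result"
  )
}

#' @export
print.equilibration_result <- function(x, ...) {
  cat(sprintf(
    "<equilibration_result> t0 = %d, g = %.3f, stride %d, %d decorrelated (n_eff %.1f)%s\n",
    x$t0_index, x$g, as.integer(ceiling(x$g)), length(x$decorrelated_indices),
    x$n_effective, if (x$zero_variance) " [zero variance]" else ""
  ))
  invisible(x)
}

#' Materialize the decorrelated series
#'
#' Extracts the decorrelated samples selected by [detect_equilibration()]
#' into a new [gradient_series()] whose sampling interval is scaled by the
#' subsampling stride.
#'
#' @param series The original [gradient_series()].
#' @param eq The matching `equilibration_result`.
#' @return A [gradient_series()] holding the decorrelated samples.
#' @export
subsample <- function(series, eq) {
  stopifnot(inherits(series, "gradient_series"),
            inherits(eq, "equilibration_result"))
  idx <- eq$decorrelated_indices
  n <- length(series$values)
  if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
    stop("decorrelated indices out of range for this series", call. = FALSE)
  }
  stride <- as.integer(ceiling(eq$g))
  gradient_series(
    values = series$values[idx],
    sampling_interval = series$sampling_interval * stride,
    lambda_value = series$lambda_value,
    start_time = series$start_time + (eq$t0_index - 1L) * series$sampling_interval,
    label = series$label
  )
}
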