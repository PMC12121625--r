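#' Split a series chronologically in half
#'
#' The first half receives `floor(N/2)` samples; for odd N the second half
#' keeps the extra sample.
#'
#' @param values Numeric vector of length >= 2.
#' @return A list with components `first` and `second`.
#' @export
split_halves <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 samples to split in half", call. = FALSE)
  k <- n %/% 2L
  list(first = values[seq_len(k)], second = values[(k + 1L):n])
}

#' Equal-width histogram pair over a pooled range
#'
#' Bins both halves into `n_bins` equally spaced bins spanning the pooled
#' minimum and maximum of the two halves, so that the two probability vectors
#' are directly comparable. The rightmost bin is closed. A pooled range of
#' zero width is degenerate: all mass goes into a single bin for both halves
#' (flagged via attribute `degenerate`).
#'
#' @param first,second Nonempty numeric vectors.
#' @param n_bins Number of bins, >= 2. Default 7.
#' @return A list with `edges` (length `n_bins + 1`), `P` and `Q`
#'   (probability vectors for the first and second halves).
#' @export
histogram_pair <- function(first, second, n_bins = 7) {
  if (!length(first) || !length(second)) {
    stop("both halves must be nonempty", call. = FALSE)
  }
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  pooled <- range(c(first, second))
  degenerate <- pooled[1] == pooled[2]
  if (degenerate) {
    # widen artificially so cut() is well defined; all mass lands in one bin
    pooled <- pooled + c(-0.5, 0.5)
  }
  edges <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
  count <- function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, nbins = n_bins)
  }
  out <- list(edges = edges,
              P = count(first) / length(first),
              Q = count(second) / length(second))
  attr(out, "degenerate") <- degenerate
  out
}

#' Jensen-Shannon distance between two probability vectors
#'
#' Computes the square root of the Jensen-Shannon divergence
#' \deqn{JS(P\|Q) = \tfrac12 D(P\|M) + \tfrac12 D(Q\|M), \quad M = \tfrac12 (P + Q),}
#' with Kullback-Leibler divergences taken in base-2 logarithms so that the
#' distance is bounded in \[0, 1\]. Terms with \eqn{P_i = 0} contribute zero.
#'
#' @param P,Q Nonnegative probability vectors of equal length, each summing
#'   to 1 (within 1e-8).
#' @return The JS distance, a number in \[0, 1\].
#' @examples
#' js_distance(c(0.5, 0.5), c(1, 0))  # ~0.558
#' @export
js_distance <- function(P, Q) {
  P <- as.numeric(P); Q <- as.numeric(Q)
  if (length(P) != length(Q)) stop("P and Q must have equal length", call. = FALSE)
  if (any(P < 0) || any(Q < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(P) - 1) > 1e-8 || abs(sum(Q) - 1) > 1e-8) {
    stop("P and Q must each sum to 1", call. = FALSE)
  }
  M <- (P + Q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / M[i]))
  }
  jsd <- (kl(P) + kl(Q)) / 2
  sqrt(max(min(jsd, 1), 0))
}

#' Convergence assessment of a raw window series
#'
#' One pass of the per-window convergence test: the raw series is
#' equilibrated ([detect_equilibration()]), decorrelated ([subsample()]),
#' split chronologically in half, each half binned into `cfg$n_bins` equally
#' spaced bins over the pooled range, and the Jensen-Shannon distance between
#' the two histograms computed. The decision is then
#' \itemize{
#'   \item `converged` if JS <= threshold and the decorrelated sample count
#'     is at least `cfg$min_decorrelated`;
#'   \item otherwise `soft_cap_stop` if the cumulative time has reached
#'     `cfg$soft_cap` and strictly more than `cfg$min_decorrelated`
#'     decorrelated samples were collected;
#'   \item otherwise `hard_cap_stop` if the cumulative time has reached
#'     `cfg$hard_cap`;
#'   \item otherwise `extend`.
#' }
#' If fewer than 2 decorrelated samples remain the JS distance is undefined
#' (`NA`) and the run can only extend or stop at the hard cap.
#'
#' @param series Raw (unequilibrated) [gradient_series()] for the window.
#' @param cfg A [protocol_config()].
#' @param total_time Cumulative production time of the window, ns.
#' @return An object of class `convergence_report`.
#' @export
assess <- function(series, cfg, total_time) {
  stopifnot(inherits(series, "gradient_series"),
            inherits(cfg, "protocol_config"),
            is.numeric(total_time), length(total_time) == 1L, total_time >= 0)

  eq <- detect_equilibration(series)
  dec <- subsample(series, eq)
  n_dec <- length(dec$values)

  if (n_dec < 2L) {
    js <- NA_real_
    hist <- list(edges = NULL, P = NULL, Q = NULL)
  } else {
    halves <- split_halves(dec$values)
    hist <- histogram_pair(halves$first, halves$second, cfg$n_bins)
    js <- js_distance(hist$P, hist$Q)
  }

  decision <- .stop_decision(js, n_dec, total_time, cfg)

  structure(
    list(
      js_distance = js,
      n_decorrelated = n_dec,
      bin_edges = hist$edges,
      first_half_probs = hist$P,
      second_half_probs = hist$Q,
      decision = decision,
      threshold_used = cfg$js_threshold,
      total_time = total_time,
      equilibration = eq
    ),
    class = "convergence_report"
  )
}

# The stopping rule as a pure function of (js, n_decorrelated, total_time, cfg).
# A tie at exactly the threshold counts as converged; the soft cap demands
# strictly more than the minimum sample count.
.stop_decision <- function(js, n_dec, total_time, cfg) {
  if (!is.na(js) && js <= cfg$js_threshold && n_dec >= cfg$min_decorrelated) {
    "converged"
  } else if (total_time >= cfg$soft_cap && n_dec > cfg$min_decorrelated) {
    "soft_cap_stop"
  } else if (total_time >= cfg$hard_cap) {
    "hard_cap_stop"
  } else {
    "extend"
  }
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "<convergence_report> JS = %s (threshold %g), %d decorrelated, t = %g ns -> %s\n",
    if (is.na(x$js_distance)) "NA" else sprintf("%.4f", x$js_distance),
    x$threshold_used, x$n_decorrelated, x$total_time, x$decision
  ))
  invisible(x)
}
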