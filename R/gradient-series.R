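#' Gradient time series for one lambda window
#'
#' Container for the dV/dlambda gradient stream emitted by a single
#' lambda-window simulation. Times are implicit: sample \eqn{i} (1-based in R)
#' sits at `start_time + (i - 1) * sampling_interval` nanoseconds.
#'
#' @param values Numeric vector of dV/dlambda samples, kcal/mol. May be empty.
#' @param sampling_interval Sampling interval in ns; must be > 0.
#' @param lambda_value Coupling parameter lambda in \[0, 1\].
#' @param start_time Time of the first sample, ns. Default 0.
#' @param label Free-text identifier (window/step/replicate). Default "".
#'
#' @return An object of class `gradient_series`.
#' @examples
#' gs <- gradient_series(rnorm(100), sampling_interval = 0.001, lambda_value = 0.5)
#' length(gs$values)
#' @export
gradient_series <- function(values, sampling_interval, lambda_value = 0,
                            start_time = 0, label = "") {
  values <- as.numeric(values)
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      !is.finite(sampling_interval) || sampling_interval <= 0) {
    stop("`sampling_interval` must be a single positive number (ns)", call. = FALSE)
  }
  if (!is.numeric(lambda_value) || length(lambda_value) != 1L ||
      !is.finite(lambda_value) || lambda_value < 0 || lambda_value > 1) {
    stop("`lambda_value` must be a single number in [0, 1]", call. = FALSE)
  }
  if (length(values) && any(!is.finite(values))) {
    stop("`values` must all be finite", call. = FALSE)
  }
  structure(
    list(
      lambda_value = lambda_value,
      sampling_interval = as.numeric(sampling_interval),
      values = values,
      start_time = as.numeric(start_time),
      label = as.character(label)
    ),
    class = "gradient_series"
  )
}

#' @export
print.gradient_series <- function(x, ...) {
  cat(sprintf(
    "<gradient_series> lambda = %g, n = %d, dt = %g ns, span = %g ns%s\n",
    x$lambda_value, length(x$values), x$sampling_interval,
    length(x$values) * x$sampling_interval,
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  ))
  invisible(x)
}

#' @export
length.gradient_series <- function(x) length(x$values)

#' Sample times of a gradient series
#'
#' @param x A `gradient_series`.
#' @return Numeric vector of sample times in ns.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "gradient_series"))
  if (!length(x$values)) return(numeric(0))
  x$start_time + (seq_along(x$values) - 1L) * x$sampling_interval
}

#' Total simulated span of a gradient series, ns
#'
#' @param x A `gradient_series`.
#' @return Duration covered by the samples (n * dt), ns.
#' @export
series_duration <- function(x) {
  stopifnot(inherits(x, "gradient_series"))
  length(x$values) * x$sampling_interval
}
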