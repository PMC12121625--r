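#' Run the adaptive sampling loop for one lambda window
#'
#' Implements the per-window on-the-fly resource allocation loop: generate an
#' initial production block of `cfg$initial_length` ns, assess convergence
#' ([assess()]), and while the decision is `extend`, generate a further
#' `cfg$additional_length` ns and reassess on the full accumulated series.
#' The loop stops when the window converges (JS distance at or below the
#' threshold with enough decorrelated samples), reaches the soft cap with
#' more than the minimum decorrelated samples, or reaches the hard cap.
#' Cap checks happen only at assessment points, so a window always completes
#' its current block.
#'
#' @param sampler A fresh sampler honouring the sampler contract (see
#'   [make_sampler()]): `extend(duration)` returns the newly generated
#'   samples and repeated calls append contiguously in time.
#' @param cfg A [protocol_config()].
#' @param lambda_value Lambda value recorded in the audit trail. Default 0.
#' @return An object of class `window_run_record` with the protocol, the
#'   per-iteration convergence reports, `stop_reason` (one of `"converged"`,
#'   `"soft_cap"`, `"hard_cap"`), `total_time` (ns), the seed, and the full
#'   accumulated [gradient_series()].
#' @examples
#' s <- make_sampler(generator_spec("iid_gaussian", mean = 5, seed = 7))
#' rec <- run_window(s, protocol_preset("A"))
#' rec$stop_reason; rec$total_time
#' @export
run_window <- function(sampler, cfg, lambda_value = 0) {
  stopifnot(inherits(sampler, "gradient_sampler") || is.list(sampler),
            inherits(cfg, "protocol_config"))
  if (!is.function(sampler$extend)) stop("sampler must provide extend()", call. = FALSE)
  dt <- sampler$sampling_interval

  values <- sampler$extend(cfg$initial_length)
  total_time <- cfg$initial_length
  iterations <- list()

  repeat {
    series <- gradient_series(values, dt, lambda_value = lambda_value)
    report <- tryCatch(
      assess(series, cfg, total_time),
      error = function(e) {
        stop(sprintf("window assessment failed at t = %g ns: %s",
                     total_time, conditionMessage(e)), call. = FALSE)
      }
    )
    iterations[[length(iterations) + 1L]] <-
      list(total_time = total_time, report = report)
    if (report$decision != "extend") break
    values <- c(values, sampler$extend(cfg$additional_length))
    total_time <- total_time + cfg$additional_length
  }

  stop_reason <- c(converged = "converged",
                   soft_cap_stop = "soft_cap",
                   hard_cap_stop = "hard_cap")[[report$decision]]
  structure(
    list(
      lambda_value = lambda_value,
      protocol = cfg,
      iterations = iterations,
      stop_reason = stop_reason,
      total_time = total_time,
      seed = sampler$seed,
      series = gradient_series(values, dt, lambda_value = lambda_value)
    ),
    class = "window_run_record"
  )
}

#' @export
print.window_run_record <- function(x, ...) {
  last <- x$iterations[[length(x$iterations)]]$report
  cat(sprintf(
    "<window_run_record> lambda = %g, protocol %s: %d assessment(s), %g ns -> %s (final JS %s, %d decorrelated)\n",
    x$lambda_value, x$protocol$name, length(x$iterations), x$total_time,
    x$stop_reason,
    if (is.na(last$js_distance)) "NA" else sprintf("%.4f", last$js_distance),
    last$n_decorrelated
  ))
  invisible(x)
}

#' Run a full alchemical transformation across lambda windows
#'
#' Runs [run_window()] independently for every node of a lambda schedule,
#' then estimates the free energy difference: each window's final series is
#' equilibrated and decorrelated, its mean and bootstrap standard error are
#' computed, and the window means are combined through the schedule weights
#' ([ti_integrate()]). Windows are fully independent — no information is
#' shared between them.
#'
#' @param samplers A list of fresh samplers, one per schedule node.
#' @param cfg A [protocol_config()].
#' @param schedule A [lambda_schedule()] with as many nodes as samplers.
#' @param n_boot Bootstrap resamples per window. Default 1000.
#' @param boot_seed Seed for the bootstrap resampling. Default 1.
#' @return A list with `records` (per-window `window_run_record`s) and
#'   `result` (a `free_energy_result`).
#' @export
run_transformation <- function(samplers, cfg, schedule, n_boot = 1000,
                               boot_seed = 1) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  n <- length(schedule$lambdas)
  if (length(samplers) != n) {
    stop(sprintf("need one sampler per schedule node (%d)", n), call. = FALSE)
  }
  records <- vector("list", n)
  means <- errs <- numeric(n)
  for (i in seq_len(n)) {
    records[[i]] <- run_window(samplers[[i]], cfg,
                               lambda_value = schedule$lambdas[i])
    eq <- detect_equilibration(records[[i]]$series)
    dec <- subsample(records[[i]]$series, eq)
    bm <- bootstrap_mean(dec$values, n_boot = n_boot,
                         seed = boot_seed + i)
    means[i] <- bm$mean
    errs[i] <- bm$std_err
  }
  list(records = records,
       result = ti_integrate(schedule, means, errs))
}
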