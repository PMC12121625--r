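#' Accuracy metrics of predicted vs reference free energies
#'
#' @param predicted,reference Equal-length numeric vectors, kcal/mol.
#' @return A list with `mae` (mean absolute error), `rmse` (root mean
#'   squared error), and `r2` (squared Pearson correlation; `NA` when fewer
#'   than 2 pairs or either vector is constant).
#' @examples
#' error_metrics(c(0, 2), c(0, 0))   # MAE 1, RMSE sqrt(2)
#' @export
error_metrics <- function(predicted, reference) {
  predicted <- as.numeric(predicted); reference <- as.numeric(reference)
  n <- length(predicted)
  if (n == 0L || n != length(reference)) {
    stop("predicted and reference must have equal nonzero length", call. = FALSE)
  }
  d <- predicted - reference
  r2 <- if (n < 2L || stats::sd(predicted) == 0 || stats::sd(reference) == 0) {
    NA_real_
  } else {
    stats::cor(predicted, reference)^2
  }
  list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)), r2 = r2)
}

#' Permutation significance of MAE and RMSE
#'
#' Shuffles the reference labels `n_perm` times, recomputing MAE and RMSE
#' each time, and reports the fraction of permuted metrics strictly below the
#' observed value — the empirical percentile of the observed metric within
#' the permutation null. Small percentiles mean the agreement is far better
#' than chance pairing.
#'
#' @param predicted,reference Numeric vectors, length >= 3.
#' @param n_perm Number of permutations, >= 1. Default 10000.
#' @param seed Integer seed. Default 1.
#' @return A list with the observed `mae`/`rmse` and their
#'   `mae_percentile`/`rmse_percentile` under the permutation null.
#' @export
permutation_test <- function(predicted, reference, n_perm = 10000, seed = 1) {
  predicted <- as.numeric(predicted); reference <- as.numeric(reference)
  n <- length(predicted)
  if (n < 3L || n != length(reference)) {
    stop("need at least 3 prediction/reference pairs", call. = FALSE)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  obs <- error_metrics(predicted, reference)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    ref_p <- reference[sample.int(n)]
    d <- predicted - ref_p
    c(mean(abs(d)), sqrt(mean(d^2)))
  }, numeric(2))
  list(mae = obs$mae, rmse = obs$rmse,
       mae_percentile = mean(perm[1, ] < obs$mae),
       rmse_percentile = mean(perm[2, ] < obs$rmse))
}

#' Replicate table of free energy estimates
#'
#' @param data A data.frame with columns `transformation`, `replicate`,
#'   `value` (kcal/mol) and optionally `reference` (one value per
#'   transformation, kcal/mol).
#' @return An object of class `replicate_table`: a list of per-transformation
#'   replicate vectors plus the reference vector.
#' @export
replicate_table <- function(data) {
  need <- c("transformation", "replicate", "value")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop(sprintf("need a data.frame with columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  labs <- unique(as.character(data$transformation))
  values <- lapply(labs, function(l) {
    v <- data$value[data$transformation == l]
    if (!length(v) || any(!is.finite(v))) {
      stop(sprintf("transformation %s needs >= 1 finite replicate", l),
           call. = FALSE)
    }
    v
  })
  names(values) <- labs
  refs <- NULL
  if ("reference" %in% names(data)) {
    refs <- vapply(labs, function(l) {
      r <- unique(data$reference[data$transformation == l])
      if (length(r) != 1L || !is.finite(r)) {
        stop(sprintf("transformation %s needs a single finite reference", l),
             call. = FALSE)
      }
      r
    }, numeric(1))
  }
  structure(list(values = values, reference = refs), class = "replicate_table")
}

#' Batch-resampled accuracy metric distributions
#'
#' Emulates running `batch_size` replicates per transformation: each sample
#' draws `batch_size` replicates without replacement within every
#' transformation, averages them, and computes MAE, RMSE and R-squared
#' against the references. When only one combination exists per
#' transformation (batch size equals the replicate count) the single
#' deterministic sample is returned.
#'
#' @param table A [replicate_table()] with references.
#' @param batch_size Replicates averaged per transformation; at most the
#'   smallest per-transformation replicate count.
#' @param n_samples Monte Carlo samples. Default 10000.
#' @param seed Integer seed. Default 1.
#' @return An object of class `metric_distribution` with the metric sample
#'   vectors and their summaries.
#' @export
batch_resample <- function(table, batch_size, n_samples = 10000, seed = 1) {
  stopifnot(inherits(table, "replicate_table"))
  if (is.null(table$reference)) {
    stop("replicate table has no reference values", call. = FALSE)
  }
  counts <- lengths(table$values)
  if (batch_size < 1L || batch_size > min(counts)) {
    stop(sprintf("batch_size must be in [1, %d]", min(counts)), call. = FALSE)
  }
  single <- all(choose(counts, batch_size) == 1)
  n_draw <- if (single) 1L else as.integer(n_samples)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  ref <- table$reference
  mae <- rmse <- r2 <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    means <- vapply(table$values, function(v) {
      mean(v[sample.int(length(v), batch_size)])
    }, numeric(1))
    m <- error_metrics(means, ref)
    mae[i] <- m$mae; rmse[i] <- m$rmse; r2[i] <- m$r2
  }
  structure(
    list(batch_size = as.integer(batch_size), mae = mae, rmse = rmse, r2 = r2,
         summary = list(
           mae_mean = mean(mae), mae_se = stats::sd(mae),
           rmse_mean = mean(rmse), rmse_se = stats::sd(rmse),
           r2_mean = mean(r2, na.rm = TRUE))),
    class = "metric_distribution"
  )
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf(
    "<metric_distribution> batch size %d, %d samples: MAE %.3f, RMSE %.3f, R2 %.3f\n",
    x$batch_size, length(x$mae), x$summary$mae_mean, x$summary$rmse_mean,
    x$summary$r2_mean))
  invisible(x)
}

#' Free energy estimates from truncated gradients
#'
#' Re-estimates the free energy difference after truncating every window's
#' gradient series at each requested time: per truncation point and
#' replicate, each window keeps only the samples before the truncation time
#' (series shorter than the truncation contribute their full length), is
#' re-equilibrated and decorrelated, and its mean feeds the schedule
#' integration. Results are averaged across replicates.
#'
#' @param replicates A list of replicates; each replicate is a list of
#'   [gradient_series()] objects, one per schedule node.
#' @param schedule A [lambda_schedule()].
#' @param times Truncation times, ns (each must leave at least 4 samples in
#'   every window).
#' @return A data.frame with columns `requested_ns`, `used_ns` (clamped to
#'   the shortest available series), `dg_mean`, `dg_se`, `n_replicates`.
#' @export
truncation_analysis <- function(replicates, schedule, times) {
  stopifnot(inherits(schedule, "lambda_schedule"), length(replicates) >= 1L)
  n_nodes <- length(schedule$lambdas)
  for (rep in replicates) {
    if (length(rep) != n_nodes) {
      stop("every replicate needs one series per schedule node", call. = FALSE)
    }
  }
  out <- lapply(times, function(tau) {
    dgs <- vapply(replicates, function(rep) {
      means <- vapply(rep, function(s) {
        n_keep <- min(length(s$values),
                      as.integer(round(tau / s$sampling_interval)))
        if (n_keep < 4L) {
          stop(sprintf("truncation at %g ns leaves %d samples (< 4)", tau, n_keep),
               call. = FALSE)
        }
        trunc <- gradient_series(s$values[seq_len(n_keep)],
                                 s$sampling_interval, s$lambda_value)
        eq <- detect_equilibration(trunc)
        mean(subsample(trunc, eq)$values)
      }, numeric(1))
      ti_integrate(schedule, means)$delta_g
    }, numeric(1))
    used <- min(tau, min(vapply(replicates, function(rep) {
      min(vapply(rep, series_duration, numeric(1)))
    }, numeric(1))))
    data.frame(requested_ns = tau, used_ns = used,
               dg_mean = mean(dgs),
               dg_se = if (length(dgs) > 1L) stats::sd(dgs) / sqrt(length(dgs)) else NA_real_,
               n_replicates = length(dgs))
  })
  do.call(rbind, out)
}

#' Computational savings relative to a fixed-allocation baseline
#'
#' @param total_simulated Total production time actually simulated for the
#'   transformation, ns.
#' @param baseline Baseline budget of a uniform-allocation protocol, ns
#'   (time-step cost multipliers are the caller's responsibility).
#' @return The saved fraction `1 - total/baseline`; negative when over
#'   budget.
#' @examples
#' savings(18, 120)  # 0.85
#' @export
savings <- function(total_simulated, baseline) {
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline must be > 0", call. = FALSE)
  }
  if (any(!is.finite(total_simulated)) || any(total_simulated < 0)) {
    stop("total_simulated must be >= 0", call. = FALSE)
  }
  1 - total_simulated / baseline
}
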