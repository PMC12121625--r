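#' Specification of a synthetic gradient stream
#'
#' Describes a seeded stochastic process standing in for the dV/dlambda
#' output of a lambda-window simulation. Five kinds are available:
#' \describe{
#'   \item{`iid_gaussian`}{independent draws from N(mean, sigma^2).}
#'   \item{`ar1`}{stationary first-order autoregressive process around
#'     `mean` with lag-1 coefficient `phi` and stationary standard deviation
#'     `sigma` (statistical inefficiency `1 + 2 phi / (1 - phi)`).}
#'   \item{`transient`}{an exponentially decaying offset
#'     `transient_height * exp(-t / transient_length)` on top of white noise —
#'     an unequilibrated start.}
#'   \item{`heteroscedastic`}{independent Gaussian noise whose standard
#'     deviation doubles every `sigma_doubling_time` ns — a persistently
#'     non-converging stream.}
#'   \item{`two_state`}{the mean jumps between `mean + switch_height` and
#'     `mean - switch_height` every `switch_period` ns — slow conformational
#'     exchange.}
#' }
#'
#' @param kind One of `"iid_gaussian"`, `"ar1"`, `"transient"`,
#'   `"heteroscedastic"`, `"two_state"`.
#' @param mean Stationary mean, kcal/mol. Default 0.
#' @param sigma Noise standard deviation, kcal/mol. Default 1.
#' @param phi AR(1) coefficient in \[0, 1). Default 0.
#' @param transient_height Initial offset of the transient, kcal/mol.
#' @param transient_length Decay time constant of the transient, ns.
#' @param sigma_doubling_time Doubling time of sigma for the
#'   heteroscedastic stream, ns. Default 1.
#' @param switch_period Half-period of the two-state mean switch, ns.
#' @param switch_height Mean offset of each state, kcal/mol. Default 1.
#' @param sampling_interval Sampling interval, ns. Default 0.001 (1 ps).
#' @param seed Integer seed. Streams with the same spec are identical.
#' @return An object of class `generator_spec`.
#' @seealso [make_sampler()]
#' @export
generator_spec <- function(kind, mean = 0, sigma = 1, phi = 0,
                           transient_height = 5, transient_length = 1,
                           sigma_doubling_time = 1, switch_period = 1,
                           switch_height = 1,
                           sampling_interval = 0.001, seed = 1) {
  kinds <- c("iid_gaussian", "ar1", "transient", "heteroscedastic", "two_state")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop(sprintf("unknown generator kind; valid: %s",
                 paste(kinds, collapse = ", ")), call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.finite(phi) || phi < 0 || phi >= 1) stop("phi must be in [0, 1)", call. = FALSE)
  if (!is.finite(sampling_interval) || sampling_interval <= 0) {
    stop("sampling_interval must be > 0 (ns)", call. = FALSE)
  }
  structure(
    list(kind = kind, mean = mean, sigma = sigma, phi = phi,
         transient_height = transient_height,
         transient_length = transient_length,
         sigma_doubling_time = sigma_doubling_time,
         switch_period = switch_period, switch_height = switch_height,
         sampling_interval = sampling_interval, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# Counter-based standard-normal stream: sample i (0-based) lives in block
# i %/% 1024, and each block is generated from a seed derived from
# (stream seed, block index). The value of sample i therefore depends only
# on (seed, i), never on how extend() calls were partitioned.
.raw_normals <- function(seed, from, n) {
  if (n <= 0L) return(numeric(0))
  block_size <- 1024L
  idx <- from + seq_len(n) - 1L        # 0-based absolute sample indices
  blocks <- unique(idx %/% block_size)
  out <- numeric(n)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  for (b in blocks) {
    set.seed((as.double(seed) * 1000003 + b) %% 2147483647)
    z <- stats::rnorm(block_size)
    sel <- idx %/% block_size == b
    out[sel] <- z[idx[sel] %% block_size + 1L]
  }
  out
}

#' Create a sampler from a generator specification
#'
#' Returns a stateful sampler honouring the sampler contract used by
#' [run_window()]: repeated `extend(duration)` calls append contiguous
#' samples, and the concatenated stream depends only on the spec (seed
#' included), not on how the calls were partitioned.
#'
#' @param spec A [generator_spec()].
#' @return An object of class `gradient_sampler` with elements
#'   `extend(duration)` (returns the newly generated samples),
#'   `sampling_interval`, `seed`, `spec`, `total_time()` and `reset()`.
#' @examples
#' s <- make_sampler(generator_spec("iid_gaussian", mean = 5, seed = 42))
#' x <- s$extend(0.1)  # 100 samples at the default 1 ps cadence
#' @export
make_sampler <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  dt <- spec$sampling_interval
  env <- new.env(parent = emptyenv())
  env$n <- 0L          # samples generated so far
  env$ar_state <- NA_real_

  transform <- function(z, from) {
    i <- from + seq_along(z) - 1L      # 0-based indices
    t <- i * dt                        # sample times, ns
    switch(spec$kind,
      iid_gaussian = spec$mean + spec$sigma * z,
      transient = spec$mean +
        spec$transient_height * exp(-t / spec$transient_length) +
        spec$sigma * z,
      heteroscedastic = spec$mean +
        spec$sigma * 2^(t / spec$sigma_doubling_time) * z,
      two_state = spec$mean +
        spec$switch_height * ifelse((t %/% spec$switch_period) %% 2 == 0, 1, -1) +
        spec$sigma * z,
      ar1 = {
        x <- numeric(length(z))
        innov <- sqrt(1 - spec$phi^2) * spec$sigma * z
        prev <- env$ar_state           # deviation from the mean
        for (j in seq_along(z)) {
          prev <- if (is.na(prev)) spec$sigma * z[j] else spec$phi * prev + innov[j]
          x[j] <- spec$mean + prev
        }
        env$ar_state <- prev
        x
      }
    )
  }

  extend <- function(duration) {
    if (!is.finite(duration) || duration < 0) {
      stop("duration must be >= 0 (ns)", call. = FALSE)
    }
    n_new <- as.integer(round(duration / dt))
    z <- .raw_normals(spec$seed, from = env$n, n = n_new)
    x <- transform(z, from = env$n)
    env$n <- env$n + n_new
    x
  }

  structure(
    list(
      extend = extend,
      sampling_interval = dt,
      seed = spec$seed,
      spec = spec,
      total_time = function() env$n * dt,
      reset = function() { env$n <- 0L; env$ar_state <- NA_real_; invisible(NULL) }
    ),
    class = "gradient_sampler"
  )
}

#' Check that a stream is reproducible and partition invariant
#'
#' Regenerates a stream under two different `extend()` call partitions of the
#' same total duration and verifies that the concatenated samples are
#' identical.
#'
#' @param spec A [generator_spec()].
#' @param partitions A list of numeric vectors; each vector is a sequence of
#'   `extend()` durations (ns) and all must sum to the same total.
#' @return `TRUE` if all partitions produce identical streams.
#' @export
stream_determinism_check <- function(spec, partitions = list(1, c(0.5, 0.5))) {
  stopifnot(inherits(spec, "generator_spec"), length(partitions) >= 1L)
  totals <- vapply(partitions, sum, numeric(1))
  if (max(totals) - min(totals) > 1e-12) {
    stop("all partitions must sum to the same total duration", call. = FALSE)
  }
  streams <- lapply(partitions, function(p) {
    s <- make_sampler(spec)
    unlist(lapply(p, s$extend))
  })
  all(vapply(streams[-1L], identical, logical(1), y = streams[[1L]]))
}
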