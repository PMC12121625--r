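#' Physical constants for free energy conversions
#'
#' @param R Gas constant in kcal/(mol K).
#' @param T Temperature in K.
#' @param V_std Standard-state volume in cubic Angstrom per molecule
#'   (1660.5392 A^3 corresponds to the 1 M standard state).
#'
#' @return An object of class `thermo_constants`.
#' @export
thermo_constants <- function(R = 1.98720425864083e-3, T = 300,
                             V_std = 1660.5392) {
  if (!is.finite(R) || R <= 0) stop("R must be > 0", call. = FALSE)
  if (!is.finite(T) || T <= 0) stop("T must be > 0 (kelvin)", call. = FALSE)
  if (!is.finite(V_std) || V_std <= 0) stop("V_std must be > 0", call. = FALSE)
  structure(list(R = R, T = T, V_std = V_std), class = "thermo_constants")
}

#' Adaptive sampling protocol configuration
#'
#' Bundles the knobs of the per-window stopping rule: the initial production
#' block, the fixed extension block, the Jensen-Shannon convergence threshold,
#' the minimum decorrelated sample count, and the soft/hard time caps.
#'
#' @param name Protocol label.
#' @param initial_length Initial production block per window, ns.
#' @param additional_length Extension block per window, ns.
#' @param n_windows Number of lambda windows the protocol pairs with.
#' @param js_threshold Jensen-Shannon distance convergence threshold
#'   (base-2 distance scale, so in (0, 1)). Default 0.1.
#' @param min_decorrelated Minimum decorrelated samples for convergence.
#'   Default 50.
#' @param soft_cap Soft time cap, ns: stop here if more than
#'   `min_decorrelated` decorrelated samples have been collected. Default 6.5.
#' @param hard_cap Hard time cap, ns: stop unconditionally. Default 10.5.
#' @param n_bins Histogram bins for the convergence test. Default 7.
#'
#' @return An object of class `protocol_config`.
#' @seealso [protocol_preset()] for the named presets.
#' @export
protocol_config <- function(name, initial_length, additional_length,
                            n_windows, js_threshold = 0.1,
                            min_decorrelated = 50, soft_cap = 6.5,
                            hard_cap = 10.5, n_bins = 7) {
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
    }
    as.numeric(x)
  }
  initial_length <- num1(initial_length, "initial_length")
  additional_length <- num1(additional_length, "additional_length")
  soft_cap <- num1(soft_cap, "soft_cap")
  hard_cap <- num1(hard_cap, "hard_cap")
  js_threshold <- num1(js_threshold, "js_threshold")
  if (!(additional_length > 0 && additional_length <= initial_length &&
        initial_length <= soft_cap && soft_cap <= hard_cap)) {
    stop("need 0 < additional_length <= initial_length <= soft_cap <= hard_cap",
         call. = FALSE)
  }
  if (js_threshold <= 0 || js_threshold >= 1) {
    stop("js_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (min_decorrelated < 2) stop("min_decorrelated must be >= 2", call. = FALSE)
  structure(
    list(
      name = as.character(name),
      initial_length = initial_length,
      additional_length = additional_length,
      n_windows = as.integer(n_windows),
      js_threshold = js_threshold,
      min_decorrelated = as.integer(min_decorrelated),
      soft_cap = soft_cap,
      hard_cap = hard_cap,
      n_bins = as.integer(n_bins)
    ),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(
    paste0("<protocol_config> %s: initial %g ns + %g ns blocks, %d windows\n",
           "  JS threshold %g, >= %d decorrelated samples, caps %g / %g ns, %d bins\n"),
    x$name, x$initial_length, x$additional_length, x$n_windows,
    x$js_threshold, x$min_decorrelated, x$soft_cap, x$hard_cap, x$n_bins
  ))
  invisible(x)
}

# Named presets: initial block, extension block, window count. Fields the
# preset table does not vary (threshold, sample minimum, caps, bins) take the
# shared defaults.
.protocol_table <- list(
  A   = c(initial = 2.5, additional = 0.50, windows = 9),
  B   = c(initial = 1.5, additional = 0.50, windows = 9),
  C   = c(initial = 1.0, additional = 0.25, windows = 9),
  D   = c(initial = 0.5, additional = 0.25, windows = 9),
  E   = c(initial = 3.5, additional = 0.50, windows = 9),
  C12 = c(initial = 1.0, additional = 0.25, windows = 12)
)

#' Named adaptive sampling protocol presets
#'
#' Returns one of the six benchmark protocols. Presets A-E pair with a
#' 9-point Gauss-Legendre lambda schedule and differ only in the initial and
#' additional simulation block lengths; C12 pairs with the 12-point schedule.
#'
#' @param name One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"C12"`.
#' @return A [protocol_config()].
#' @examples
#' protocol_preset("A")
#' protocol_preset("C12")$n_windows
#' @export
protocol_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.protocol_table)) {
    stop(sprintf("unknown protocol %s; valid presets: %s",
                 deparse(substitute(name)),
                 paste(names(.protocol_table), collapse = ", ")),
         call. = FALSE)
  }
  row <- .protocol_table[[name]]
  protocol_config(name, initial_length = row[["initial"]],
                  additional_length = row[["additional"]],
                  n_windows = row[["windows"]])
}

#' Standard binding free energy from a dissociation constant
#'
#' Converts an equilibrium dissociation constant into a standard binding free
#' energy, `dG = R T ln(Kd)` with Kd in molar units, so Kd < 1 M gives a
#' negative (favourable) free energy.
#'
#' @param kd Dissociation constant, molar. Must be > 0.
#' @param tc A [thermo_constants()] object.
#' @return Free energy in kcal/mol.
#' @examples
#' dg_from_kd(1e-6)  # a micromolar binder at 300 K
#' @export
dg_from_kd <- function(kd, tc = thermo_constants()) {
  stopifnot(inherits(tc, "thermo_constants"))
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0)) {
    stop("`kd` must be positive and finite (molar)", call. = FALSE)
  }
  tc$R * tc$T * log(kd)
}
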