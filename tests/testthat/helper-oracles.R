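# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Direct evaluation of the Jensen-Shannon distance from its definition:
# sqrt(1/2 D(P||M) + 1/2 D(Q||M)), base-2 KL, M = (P+Q)/2.
js_oracle <- function(P, Q) {
  M <- (P + Q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  sqrt((kl(P, M) + kl(Q, M)) / 2)
}

# Naive O(N^2-ish) statistical inefficiency: explicit lag loop with the
# initial-positive-sequence truncation.
g_oracle <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  c0 <- sum(xc^2) / n
  if (c0 == 0) return(1)
  g <- 1
  for (tau in 1:(n - 1)) {
    rho <- sum(xc[1:(n - tau)] * xc[(tau + 1):n]) / n / c0
    if (rho <= 0) break
    g <- g + 2 * (1 - tau / n) * rho
  }
  max(g, 1)
}

# Exhaustive equilibration-cut search: every admissible t0, naive g.
aed_oracle <- function(x) {
  n <- length(x)
  best <- list(neff = -Inf, t0 = NA, g = NA)
  for (t0 in 0:(n - 4)) {
    g <- g_oracle(x[(t0 + 1):n])
    neff <- (n - t0) / g
    if (neff > best$neff) best <- list(neff = neff, t0 = t0 + 1, g = g)
  }
  best
}

# Numerical configurational integral for the six-dimensional harmonic
# virtual-bond restraint, by one-dimensional quadrature per coordinate
# (the integrand separates). Energies follow the k/2 x^2 convention.
boresch_oracle <- function(p) {
  RT <- p$tc$R * p$tc$T
  I_r <- stats::integrate(function(r) r^2 * exp(-p$k_r * (r - p$r0)^2 / (2 * RT)),
                          0, Inf, rel.tol = 1e-10)$value
  I_th <- function(k, th0) {
    stats::integrate(function(th) sin(th) * exp(-k * (th - th0)^2 / (2 * RT)),
                     0, pi, rel.tol = 1e-10)$value
  }
  I_phi <- function(k) {
    stats::integrate(function(phi) exp(-k * phi^2 / (2 * RT)),
                     -pi, pi, rel.tol = 1e-10)$value
  }
  Z <- I_r * I_th(p$k_thetaA, p$theta_A) * I_th(p$k_thetaB, p$theta_B) *
    I_phi(p$k_phiA) * I_phi(p$k_phiB) * I_phi(p$k_phiC)
  -RT * log(8 * pi^2 * p$tc$V_std / Z)
}

# The six published ABFE table rows (overall, complex, solvated, restraint
# addition; kcal/mol) used to pin down the cycle sign convention.
abfe_reference_rows <- function() {
  data.frame(
    overall   = c(-8.21, -7.65, -7.85, -8.50, -8.64, -8.59),
    complex   = c(31.02, 30.50, 30.71, 31.42, 31.61, 31.56),
    solvated  = c(17.32, 17.33, 17.32, 17.10, 17.15, 17.14),
    restraint = c(2.02, 1.97, 1.97, 1.68, 1.69, 1.67)
  )
}

# A synthetic replicate table: noisy measurements around known references.
make_replicate_table <- function(n_transform = 8, n_rep = 10, noise = 0.5,
                                 seed = 1) {
  set.seed(seed)
  truth <- rnorm(n_transform, sd = 2)
  df <- expand.grid(replicate = seq_len(n_rep),
                    transformation = paste0("T", seq_len(n_transform)))
  df$reference <- truth[as.integer(factor(df$transformation,
                                          levels = unique(df$transformation)))]
  df$value <- df$reference + rnorm(nrow(df), sd = noise)
  replicate_table(df)
}
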