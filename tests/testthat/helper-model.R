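# Shared fixtures: baseline parameter sets and small numerical oracles.

baseline <- function(mu1 = 0.1, mu2 = 0.1, epsilon = 1) {
  model_params(mu1 = mu1, mu2 = mu2, epsilon = epsilon)
}

# central finite-difference Jacobian of plankton_rhs (independent oracle)
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    J[, j] <- (plankton_rhs(state + e, params) -
                 plankton_rhs(pmax(state - e, 0), params)) / (2 * h)
  }
  J
}

# random admissible interior states, fixed seed per call site
random_states <- function(n, lo = 0.05, hi = 3) {
  matrix(stats::runif(3 * n, lo, hi), ncol = 3)
}

# sign-change scan for positive roots of a polynomial (oracle for the
# zooplankton-free quartic)
scan_poly_roots <- function(coefs, lo = 1e-4, hi = 100, n = 200000L) {
  f <- function(x) {
    acc <- 0
    for (k in rev(seq_along(coefs))) acc <- acc * x + coefs[k]
    acc
  }
  xs <- seq(lo, hi, length.out = n)
  ys <- f(xs)
  roots <- c()
  for (i in seq_len(n - 1L))
    if (is.finite(ys[i]) && is.finite(ys[i + 1L]) && ys[i] * ys[i + 1L] < 0)
      roots <- c(roots, stats::uniroot(f, c(xs[i], xs[i + 1L]), tol = 1e-12)$root)
  roots
}

# brute-force count/location of fast-subsystem equilibria: cells of a
# sign grid of (F, G) where both components straddle zero
grid_scan_fast <- function(v0, params, n = 400L, lim = 5) {
  cs <- seq(lim / n, lim, length.out = n)
  us <- seq(lim / n, lim, length.out = n)
  Fm <- outer(cs, us, function(c_, u)
    params$A * u / (c_ + 1) - params$delta * u * c_ / (c_ + params$c2) -
      params$nu * c_ * v0 / (c_ + params$c3) - c_)
  Gm <- outer(cs, us, function(c_, u)
    (params$B * c_ / (c_ + params$c1) - u) * u - u * v0 / (u + params$h) -
      params$sigma * u)
  hits <- NULL
  for (i in seq_len(n - 1L)) for (j in seq_len(n - 1L)) {
    fc <- Fm[i:(i + 1L), j:(j + 1L)]; gc <- Gm[i:(i + 1L), j:(j + 1L)]
    if (min(fc) < 0 && max(fc) > 0 && min(gc) < 0 && max(gc) > 0)
      hits <- rbind(hits, c(mean(cs[i:(i + 1L)]), mean(us[j:(j + 1L)])))
  }
  if (is.null(hits)) return(hits)
  # merge adjacent cells into clusters; near the fold the nullclines are
  # close to tangent, so near-miss cells within a few widths are one hit
  tolm <- 4.5 * lim / n
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) if (keep[i]) {
    for (j in seq_len(nrow(hits))) if (j != i && keep[j] &&
                                       max(abs(hits[i, ] - hits[j, ])) < tolm)
      keep[j] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

trapz_mass <- function(z, dx) dx * (sum(z) - (z[1] + z[length(z)]) / 2)
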