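# Linear spatial stability about a homogeneous coexistence state.
#
# Perturbations ~ exp(lambda t) cos(k x) of the reaction-diffusion system
# (diffusivities 1, 1, D) satisfy a cubic dispersion relation
# lambda^3 + p2(k^2) lambda^2 + p1(k^2) lambda + p0(k^2) = 0 whose
# coefficients are polynomials in k^2 built from the (epsilon-scaled)
# Jacobian at the steady state. Note the third Jacobian row carries the
# epsilon factor, so the Turing verdict and critical wavenumber depend on
# the timescale separation.

eq_coords <- function(equilibrium) {
  if (inherits(equilibrium, "equilibrium")) equilibrium$coords
  else as.numeric(equilibrium)
}

dispersion_coeffs <- function(J, D, k2) {
  M11 <- det(J[2:3, 2:3]); M22 <- det(J[c(1, 3), c(1, 3)]); M33 <- det(J[1:2, 1:2])
  trJ <- sum(diag(J)); dtJ <- det(J)
  p2 <- (2 + D) * k2 - trJ
  p1 <- (1 + 2 * D) * k2^2 -
    ((J[2, 2] + J[3, 3]) + (J[1, 1] + J[3, 3]) + D * (J[1, 1] + J[2, 2])) * k2 +
    (M11 + M22 + M33)
  p0 <- D * k2^3 - ((J[1, 1] + J[2, 2]) * D + J[3, 3]) * k2^2 +
    (M11 + M22 + M33 * D) * k2 - dtJ
  list(p2 = p2, p1 = p1, p0 = p0)
}

max_re_root <- function(p2, p1, p0) {
  max(Re(polyroot(c(p0, p1, p2, 1))))
}

#' Dispersion relation of the spatial model
#'
#' Evaluates the coefficients `p2(k^2), p1(k^2), p0(k^2)` of the cubic
#' dispersion relation and the maximal real part of its roots over a grid
#' of squared wavenumbers. At `k^2 = 0` the coefficients reduce to the
#' temporal Routh--Hurwitz coefficients of the steady state.
#'
#' @param params a [model_params()] object.
#' @param D zooplankton-to-turbulent diffusivity ratio (> 0).
#' @param equilibrium a coexistence `"equilibrium"` object or its `c(c,u,v)`
#'   coordinates (steady-state residual below `1e-9`).
#' @param k2_grid squared-wavenumber grid (default 2000 log-spaced points
#'   on `[1e-4, 10]`).
#' @return An object of class `"dispersion_data"`: the grid, coefficient
#'   arrays, `max_re_lambda`, and (when the instability is present) the
#'   critical wavenumber `kT2` with its discriminant `Lambda`.
#' @export
dispersion <- function(params, D, equilibrium,
                       k2_grid = exp(seq(log(1e-4), log(10), length.out = 2000L))) {
  stopifnot(D > 0)
  x <- eq_coords(equilibrium)
  if (any(x <= 0))
    stop("dispersion analysis requires a coexistence (interior) state",
         call. = FALSE)
  if (max(abs(plankton_rhs(x, params))) > 1e-9)
    stop("equilibrium residual above 1e-9", call. = FALSE)
  J <- plankton_jacobian(x, params)
  co <- dispersion_coeffs(J, D, k2_grid)
  mre <- vapply(seq_along(k2_grid), function(i)
    max_re_root(co$p2[i], co$p1[i], co$p0[i]), numeric(1))
  kt <- critical_wavenumber(params, D, x)
  structure(list(k2_grid = k2_grid, p2 = co$p2, p1 = co$p1, p0 = co$p0,
                 max_re_lambda = mre,
                 kT2 = if (is.null(kt)) NA_real_ else kt$kT2,
                 Lambda = if (is.null(kt)) NA_real_ else kt$Lambda,
                 jacobian = J, D = D),
            class = "dispersion_data")
}

#' @rdname dispersion
#' @param x a `"dispersion_data"`.
#' @param path CSV output path.
#' @export
write_dispersion_csv <- function(x, path) {
  utils::write.csv(data.frame(k2 = x$k2_grid, p2 = x$p2, p1 = x$p1,
                              p0 = x$p0, max_re_lambda = x$max_re_lambda),
                   path, row.names = FALSE)
  invisible(path)
}

#' Critical Turing wavenumber
#'
#' Closed-form location of the local minimum of `p0(k^2)`:
#' `kT^2 = (J11 + J22)/3 + (J33 + sqrt(Lambda))/(3 D)` with
#' `Lambda = (J11^2 + J22^2 - J11 J22 + 3 J12 J21) D^2 +
#'  D (3 J13 J31 + 3 J23 J32 - J11 J33 - J22 J33) + J33^2`.
#' The value is returned only when it is real, positive, and
#' `p0(kT^2) <= 1e-8` (at or beyond the instability threshold), and it is
#' cross-validated against a direct numerical minimization of `p0` over
#' `k^2 in (0, 10]`.
#'
#' @inheritParams dispersion
#' @return `NULL` when no real positive critical wavenumber exists,
#'   otherwise a list with `kT2`, `Lambda`, and `kT2_numeric` (the
#'   minimizer found numerically).
#' @export
critical_wavenumber <- function(params, D, equilibrium) {
  x <- eq_coords(equilibrium)
  J <- plankton_jacobian(x, params)
  Lambda <- (J[1, 1]^2 + J[2, 2]^2 - J[1, 1] * J[2, 2] +
               3 * J[1, 2] * J[2, 1]) * D^2 +
    D * (3 * J[1, 3] * J[3, 1] + 3 * J[2, 3] * J[3, 2] -
           J[1, 1] * J[3, 3] - J[2, 2] * J[3, 3]) + J[3, 3]^2
  if (Lambda < 0) return(NULL)
  kT2 <- (J[1, 1] + J[2, 2]) / 3 + (J[3, 3] + sqrt(Lambda)) / (3 * D)
  if (!is.finite(kT2) || kT2 <= 0) return(NULL)
  p0f <- function(k2) dispersion_coeffs(J, D, k2)$p0
  if (p0f(kT2) > 1e-8) return(NULL)
  opt <- stats::optimize(p0f, c(1e-6, 10), tol = 1e-10)
  list(kT2 = kT2, Lambda = Lambda, kT2_numeric = opt$minimum)
}

#' Turing instability verdict
#'
#' Checks the four conditions for a diffusion-driven (Turing) instability
#' of a temporally stable homogeneous state: `p2(0) > 0`, `p0(0) > 0`,
#' `p1(0) p2(0) > p0(0)`, and `p0(k^2) < 0` for some `k`. If the spatial
#' condition holds while the temporal ones fail, the state is unstable to
#' both uniform and patterned perturbations (`"turing_hopf"`).
#'
#' @inheritParams dispersion
#' @return `"turing"`, `"turing_hopf"`, or `"none"`.
#' @export
turing_check <- function(params, D, equilibrium) {
  x <- eq_coords(equilibrium)
  J <- plankton_jacobian(x, params)
  rh <- dispersion_coeffs(J, D, 0)
  temporal_ok <- rh$p2 > 0 && rh$p0 > 0 && rh$p1 * rh$p2 > rh$p0
  p0min <- stats::optimize(function(k2) dispersion_coeffs(J, D, k2)$p0,
                           c(1e-6, 10), tol = 1e-10)$objective
  spatial_unstable <- p0min < 0
  if (temporal_ok && spatial_unstable) "turing"
  else if (spatial_unstable) "turing_hopf"
  else "none"
}
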