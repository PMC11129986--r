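#' Parameter set for the plankton-oxygen model
#'
#' Constructs and validates the dimensionless parameter set of the coupled
#' oxygen--phytoplankton--zooplankton model. The defaults for the kinetic
#' constants are the baseline used throughout the analyses
#' (`A = 4, B = 3, sigma = 0.1, c1 = 0.7, c2 = 1, c3 = 1, c4 = 1, eta = 0.7,
#' delta = 1, nu = 0.01, h = 0.1`); the zooplankton mortality rates `mu1`
#' (linear) and `mu2` (quadratic, intraspecific competition / predation by
#' higher trophic levels) and the timescale-separation parameter `epsilon`
#' are the quantities one typically varies.
#'
#' @param A per capita oxygen production rate (> 0).
#' @param B per capita phytoplankton growth rate (> 0).
#' @param sigma phytoplankton natural mortality rate (> 0).
#' @param c1,c2,c3,c4 half-saturation constants of the Monod-type kinetic
#'   terms (> 0).
#' @param eta zooplankton food-assimilation coefficient (> 0).
#' @param delta oxygen consumption rate by phytoplankton (> 0).
#' @param nu oxygen consumption rate by zooplankton (> 0).
#' @param h half-saturation constant of the grazing term (> 0).
#' @param mu1 linear zooplankton mortality rate (>= 0).
#' @param mu2 quadratic zooplankton mortality coefficient (>= 0).
#' @param epsilon timescale ratio, 0 < epsilon <= 1; the zooplankton
#'   equation is multiplied by `epsilon`, so small values make zooplankton
#'   the slow variable.
#'
#' @return An object of class `"model_params"` (a named list).
#' @examples
#' p <- model_params(mu1 = 0.3, mu2 = 0.1, epsilon = 0.5)
#' plankton_rhs(c(1, 1, 1), p)
#' @export
model_params <- function(A = 4, B = 3, sigma = 0.1, c1 = 0.7, c2 = 1,
                         c3 = 1, c4 = 1, eta = 0.7, delta = 1, nu = 0.01,
                         h = 0.1, mu1 = 0, mu2 = 0, epsilon = 1) {
  p <- list(A = A, B = B, sigma = sigma, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
            eta = eta, delta = delta, nu = nu, h = h,
            mu1 = mu1, mu2 = mu2, epsilon = epsilon)
  validate_params(p)
  class(p) <- "model_params"
  p
}

validate_params <- function(p) {
  pos <- c("A", "B", "sigma", "c1", "c2", "c3", "c4", "eta", "delta", "nu", "h")
  for (nm in pos) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("parameter '", nm, "' must be a single finite positive number",
           call. = FALSE)
  }
  for (nm in c("mu1", "mu2")) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop("parameter '", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  e <- p$epsilon
  if (!is.numeric(e) || length(e) != 1L || !is.finite(e) || e <= 0 || e > 1)
    stop("parameter 'epsilon' must satisfy 0 < epsilon <= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("plankton-oxygen model parameters\n")
  cat(sprintf("  kinetics: A=%g B=%g sigma=%g c1=%g c2=%g c3=%g c4=%g\n",
              x$A, x$B, x$sigma, x$c1, x$c2, x$c3, x$c4))
  cat(sprintf("            eta=%g delta=%g nu=%g h=%g\n",
              x$eta, x$delta, x$nu, x$h))
  cat(sprintf("  mortality: mu1=%g mu2=%g   timescale: epsilon=%g\n",
              x$mu1, x$mu2, x$epsilon))
  invisible(x)
}

#' Serialize / deserialize a parameter set as flat JSON
#'
#' @param params a `model_params` object.
#' @param path file path; for `params_from_json` the file to read.
#' @return `params_from_json` returns a validated `model_params` object;
#'   `params_to_json` invisibly returns `path`.
#' @export
params_to_json <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, lapply(as.list(x), as.numeric))
}

# Clamp tiny negative components (upstream arithmetic noise) to zero;
# anything more negative, or non-finite, is a genuine error.
check_state <- function(state) {
  if (length(state) != 3L || !is.numeric(state))
    stop("state must be a numeric vector (c, u, v) of length 3", call. = FALSE)
  if (any(!is.finite(state)))
    stop("invalid state: non-finite component", call. = FALSE)
  if (any(state < -1e-12))
    stop("invalid state: negative component below -1e-12", call. = FALSE)
  pmax(state, 0)
}

#' Right-hand side of the plankton-oxygen model
#'
#' Evaluates the reaction terms of the fast-time system: oxygen production
#' and consumption `F`, phytoplankton growth and grazing `G`, and the
#' epsilon-scaled zooplankton term `epsilon * H`. `plankton_H` returns the
#' bare zooplankton reaction function `H` without the `epsilon` factor
#' (growth modulated by oxygen, minus linear and quadratic mortality).
#'
#' @param state numeric vector `c(c, u, v)`: oxygen concentration,
#'   phytoplankton density, zooplankton density (all >= 0).
#' @param params a [model_params()] object.
#' @return `plankton_rhs` returns `c(F, G, epsilon * H)`; `plankton_H`
#'   returns the scalar `H`.
#' @examples
#' p <- model_params(mu1 = 0.1, mu2 = 0.1)
#' plankton_rhs(c(0, 0, 0), p)  # the origin is an equilibrium
#' @export
plankton_rhs <- function(state, params) {
  s <- check_state(state)
  c_ <- s[1]; u <- s[2]; v <- s[3]; p <- params
  F_ <- p$A * u / (c_ + 1) - p$delta * u * c_ / (c_ + p$c2) -
    p$nu * c_ * v / (c_ + p$c3) - c_
  G_ <- (p$B * c_ / (c_ + p$c1) - u) * u - u * v / (u + p$h) - p$sigma * u
  H_ <- p$eta * c_^2 / (c_^2 + p$c4^2) * u * v / (u + p$h) -
    p$mu1 * v - p$mu2 * v^2
  c(F_, G_, p$epsilon * H_)
}

#' @rdname plankton_rhs
#' @export
plankton_H <- function(state, params) {
  s <- check_state(state)
  c_ <- s[1]; u <- s[2]; v <- s[3]; p <- params
  p$eta * c_^2 / (c_^2 + p$c4^2) * u * v / (u + p$h) -
    p$mu1 * v - p$mu2 * v^2
}

#' Analytic Jacobian of the plankton-oxygen model
#'
#' Closed-form partial derivatives of `(F, G, epsilon * H)` with respect to
#' `(c, u, v)`. The third row carries the `epsilon` factor, matching the
#' fast-time system integrated by [integrate_model()]. Set `scaled = FALSE`
#' to obtain the Jacobian of `(F, G, H)` (used internally by the equilibrium
#' solvers, whose roots do not depend on `epsilon`).
#'
#' @inheritParams plankton_rhs
#' @param scaled logical; multiply the third row by `epsilon` (default).
#' @return A 3x3 numeric matrix.
#' @export
plankton_jacobian <- function(state, params, scaled = TRUE) {
  s <- check_state(state)
  c_ <- s[1]; u <- s[2]; v <- s[3]; p <- params
  Fc <- -p$A * u / (c_ + 1)^2 - p$delta * u * p$c2 / (c_ + p$c2)^2 -
    p$nu * v * p$c3 / (c_ + p$c3)^2 - 1
  Fu <- p$A / (c_ + 1) - p$delta * c_ / (c_ + p$c2)
  Fv <- -p$nu * c_ / (c_ + p$c3)
  Gc <- p$B * p$c1 * u / (c_ + p$c1)^2
  Gu <- p$B * c_ / (c_ + p$c1) - 2 * u - v * p$h / (u + p$h)^2 - p$sigma
  Gv <- -u / (u + p$h)
  sat <- p$eta * c_^2 / (c_^2 + p$c4^2)
  Hc <- p$eta * 2 * c_ * p$c4^2 / (c_^2 + p$c4^2)^2 * u * v / (u + p$h)
  Hu <- sat * v * p$h / (u + p$h)^2
  Hv <- sat * u / (u + p$h) - p$mu1 - 2 * p$mu2 * v
  f <- if (scaled) params$epsilon else 1
  matrix(c(Fc, Fu, Fv,
           Gc, Gu, Gv,
           f * Hc, f * Hu, f * Hv), nrow = 3, byrow = TRUE)
}
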