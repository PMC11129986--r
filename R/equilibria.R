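# Steady states: extinction E0, zooplankton-free (quartic), coexistence.

# characteristic polynomial lambda^3 + p2 l^2 + p1 l + p0 of a 3x3 matrix
char_poly_coeffs <- function(J) {
  p2 <- -sum(diag(J))
  p1 <- det(J[2:3, 2:3]) + det(J[c(1, 3), c(1, 3)]) + det(J[1:2, 1:2])
  p0 <- -det(J)
  c(p0 = p0, p1 = p1, p2 = p2)
}

new_equilibrium <- function(coords, kind, eigenvalues, rh, stability) {
  structure(list(coords = coords, kind = kind, eigenvalues = eigenvalues,
                 rh = rh, stability = stability),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (%s): c=%.6g u=%.6g v=%.6g\n",
              x$kind, x$stability, x$coords[1], x$coords[2], x$coords[3]))
  cat("  eigenvalues:",
      paste(sprintf("%.4g%+.4gi", Re(x$eigenvalues), Im(x$eigenvalues)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Classify a steady state of the plankton-oxygen model
#'
#' Fills in the eigenvalues of the analytic (epsilon-scaled) Jacobian, the
#' Routh--Hurwitz coefficients `(p0, p1, p2)` of its characteristic
#' polynomial, and a stability label. The Routh--Hurwitz verdict
#' (`p0 > 0, p2 > 0, p1 p2 > p0`) is checked against the eigenvalue verdict;
#' a disagreement aborts, as it indicates a numerically marginal case.
#'
#' @param coords numeric `c(c, u, v)`; must satisfy the steady-state
#'   equations to residual `1e-6`.
#' @param params a [model_params()] object.
#' @param kind one of `"extinction"`, `"zooplankton_free"`, `"coexistence"`.
#' @return An object of class `"equilibrium"`.
#' @export
classify_equilibrium <- function(coords, params,
                                 kind = c("coexistence", "zooplankton_free",
                                          "extinction")) {
  kind <- match.arg(kind)
  res <- plankton_rhs(coords, params)
  if (max(abs(res)) > 1e-6)
    stop("coords is not an equilibrium (residual ", format(max(abs(res))), ")",
         call. = FALSE)
  J <- plankton_jacobian(coords, params)
  ev <- eigen(J, only.values = TRUE)$values
  rh <- char_poly_coeffs(J)
  if (any(abs(Re(ev)) < 1e-8))
    stop("marginal equilibrium: eigenvalue with |Re| < 1e-8 (bifurcation point)",
         call. = FALSE)
  n_unst <- sum(Re(ev) > 0)
  stability <- if (n_unst == 0) "stable"
  else if (n_unst == 3) "unstable"
  else "saddle"
  rh_stable <- rh["p0"] > 0 && rh["p2"] > 0 && rh["p1"] * rh["p2"] > rh["p0"]
  if (rh_stable != (stability == "stable"))
    stop("Routh-Hurwitz and eigenvalue verdicts disagree", call. = FALSE)
  new_equilibrium(coords, kind, ev, rh, stability)
}

# classify, but tolerate marginal points (label them instead of aborting)
classify_or_marginal <- function(coords, params, kind) {
  tryCatch(classify_equilibrium(coords, params, kind),
           error = function(e) {
             if (grepl("marginal", conditionMessage(e))) {
               J <- plankton_jacobian(coords, params)
               new_equilibrium(coords, kind,
                               eigen(J, only.values = TRUE)$values,
                               char_poly_coeffs(J), "marginal")
             } else stop(e)
           })
}

# Quartic in c for the zooplankton-free state: eliminate u via
# u = (c(B - sigma) - c1 sigma)/(c + c1) (phytoplankton balance at v = 0)
# and clear denominators in the oxygen balance. Coefficients are expanded
# exactly by polynomial arithmetic; algebraically identical to the printed
# closed form.
zf_quartic_coeffs <- function(p) {
  # un(c) = c (B - sigma) - c1 sigma   (numerator of u)
  un <- c(-p$c1 * p$sigma, p$B - p$sigma)             # a0 + a1 c
  pmul <- function(a, b) {                            # polynomial product
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
        out[i:(i + length(b) - 1L)] + a[i] * b
    out
  }
  padd <- function(a, b) {
    n <- max(length(a), length(b))
    c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  }
  # A un (c + c2) - delta c un (c + 1) - c (c + 1)(c + c2)(c + c1) = 0
  t1 <- p$A * pmul(un, c(p$c2, 1))
  t2 <- -p$delta * pmul(c(0, 1), pmul(un, c(1, 1)))
  t3 <- -pmul(pmul(c(0, 1), c(1, 1)), pmul(c(p$c2, 1), c(p$c1, 1)))
  padd(padd(t1, t2), t3)                              # degree 4, a0..a4
}

zf_u_of_c <- function(c_, p) (c_ * (p$B - p$sigma) - p$c1 * p$sigma) / (c_ + p$c1)

# 2-D Newton polish on (F, G) at v = 0
polish_zf <- function(c_, u, p, maxit = 50L) {
  for (i in seq_len(maxit)) {
    f <- plankton_rhs(c(c_, u, 0), p)[1:2]
    if (max(abs(f)) < 1e-13) break
    J <- plankton_jacobian(c(c_, u, 0), p)[1:2, 1:2]
    d <- solve(J, -f)
    c_ <- c_ + d[1]; u <- u + d[2]
  }
  c(c_, u)
}

#' Zooplankton-free steady states
#'
#' Finds all feasible steady states of the form `(c, u, 0)`: the oxygen
#' component solves a quartic (obtained by eliminating the phytoplankton
#' density from the oxygen and phytoplankton balances at zero zooplankton)
#' and the phytoplankton component follows from the linear elimination.
#' Roots are polished by 2-D Newton iteration on `(F, G)`. These states do
#' not depend on `mu1`, `mu2` or `epsilon`.
#'
#' @param params a [model_params()] object.
#' @return A list of `"equilibrium"` objects sorted by the oxygen component
#'   (possibly empty).
#' @examples
#' eqs <- find_zooplankton_free(model_params(mu1 = 0.1, mu2 = 0.1))
#' sapply(eqs, function(e) e$coords[1])  # 0.0258, 1.712
#' @export
find_zooplankton_free <- function(params) {
  p <- params
  if (p$B <= p$sigma) return(list())   # u would be negative for all c > 0
  co <- zf_quartic_coeffs(p)
  r <- polyroot(co)
  cr <- Re(r[abs(Im(r)) < 1e-8 & Re(r) > 1e-12])
  out <- list()
  for (c_ in sort(cr)) {
    u <- zf_u_of_c(c_, p)
    if (!is.finite(u) || u <= 1e-12) next
    cu <- polish_zf(c_, u, p)
    if (any(!is.finite(cu)) || any(cu <= 1e-12)) next
    out[[length(out) + 1L]] <-
      classify_or_marginal(c(cu, 0), p, "zooplankton_free")
  }
  out
}

# Newton iteration on (F, G, H); epsilon-independent roots
newton_fgh <- function(x, p, maxit = 100L, tol = 1e-12) {
  for (i in seq_len(maxit)) {
    if (any(!is.finite(x)) || any(x < -0.5)) return(NULL)
    xs <- pmax(x, 1e-14)
    f <- c(plankton_rhs(xs, p)[1:2], plankton_H(xs, p))
    if (max(abs(f)) < tol) break
    J <- plankton_jacobian(xs, p, scaled = FALSE)
    d <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    x <- xs + d
  }
  xs <- pmax(x, 1e-14)
  f <- c(plankton_rhs(xs, p)[1:2], plankton_H(xs, p))
  if (max(abs(f)) < 1e-9) xs else NULL
}

# seed the zooplankton component for a (c, u) grid point
seed_v <- function(c_, u, p) {
  if (p$mu2 > 0)
    (p$eta * c_^2 / (c_^2 + p$c4^2) * u / (u + p$h) - p$mu1) / p$mu2
  else
    (u + p$h) * (p$B * c_ / (c_ + p$c1) - u - p$sigma)
}

#' Coexistence steady states
#'
#' Finds all distinct interior steady states `(c, u, v)` with strictly
#' positive components by multi-start 3-D Newton iteration on
#' `(F, G, H) = 0`. Starting points cover a grid in the `(c, u)` plane with
#' the zooplankton component seeded from the `H = 0` elimination
#' `v = (eta c^2/(c^2 + c4^2) u/(u + h) - mu1)/mu2` when `mu2 > 0`, and from
#' the grazing balance otherwise. Duplicates are merged at Euclidean
#' tolerance `1e-7`.
#'
#' @param params a [model_params()] object; `mu1 = mu2 = 0` is rejected
#'   (the zooplankton balance then admits no isolated interior root).
#' @param c_range,u_range grid ranges for the starting points.
#' @param n_grid grid resolution per axis (default 40).
#' @return A list of `"equilibrium"` objects sorted by the oxygen component.
#' @export
find_coexistence <- function(params, c_range = c(0.05, 5),
                             u_range = c(0.05, 5), n_grid = 40L) {
  p <- params
  if (p$mu1 == 0 && p$mu2 == 0)
    stop("mu1 = mu2 = 0: interior zooplankton balance is degenerate ",
         "(no isolated coexistence states)", call. = FALSE)
  sols <- list()
  cs <- seq(c_range[1], c_range[2], length.out = n_grid)
  us <- seq(u_range[1], u_range[2], length.out = n_grid)
  for (c0 in cs) for (u0 in us) {
    v0 <- seed_v(c0, u0, p)
    if (!is.finite(v0) || v0 <= 0) next
    s <- newton_fgh(c(c0, u0, v0), p)
    if (is.null(s) || any(s < 1e-10)) next
    dup <- FALSE
    for (q in sols) if (sqrt(sum((q - s)^2)) < 1e-7) { dup <- TRUE; break }
    if (!dup) sols[[length(sols) + 1L]] <- s
  }
  sols <- sols[order(vapply(sols, `[`, numeric(1), 1L))]
  lapply(sols, classify_or_marginal, params = p, kind = "coexistence")
}

#' Extinction steady state
#'
#' The total-extinction state at the origin, classified from the analytic
#' Jacobian (diagonal eigenvalues `-1, -sigma, -epsilon mu1`); it is stable
#' whenever `mu1 > 0`.
#'
#' @param params a [model_params()] object.
#' @return An `"equilibrium"` object.
#' @export
extinction_state <- function(params) {
  classify_or_marginal(c(0, 0, 0), params, "extinction")
}

#' Tabulate steady states
#'
#' @param eqs a list of `"equilibrium"` objects (as returned by the finders).
#' @return A data frame with coordinates, eigenvalues, Routh--Hurwitz
#'   coefficients and stability labels, one row per state.
#' @export
equilibria_table <- function(eqs) {
  if (inherits(eqs, "equilibrium")) eqs <- list(eqs)
  do.call(rbind, lapply(eqs, function(e) {
    data.frame(kind = e$kind, c = e$coords[1], u = e$coords[2], v = e$coords[3],
               re_lambda1 = Re(e$eigenvalues[1]), re_lambda2 = Re(e$eigenvalues[2]),
               re_lambda3 = Re(e$eigenvalues[3]),
               im_lambda1 = Im(e$eigenvalues[1]), im_lambda2 = Im(e$eigenvalues[2]),
               im_lambda3 = Im(e$eigenvalues[3]),
               p0 = e$rh[["p0"]], p1 = e$rh[["p1"]], p2 = e$rh[["p2"]],
               stability = e$stability)
  }))
}

#' @rdname equilibria_table
#' @param path CSV output path.
#' @export
write_equilibria_csv <- function(eqs, path) {
  utils::write.csv(equilibria_table(eqs), path, row.names = FALSE)
  invisible(path)
}
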