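# Fast-subsystem analysis, critical manifold, fold point, slow flow.
#
# Freezing the zooplankton density v = v0 turns the oxygen-phytoplankton
# pair into the fast subsystem; its equilibria swept over v0 trace out the
# critical manifold of the slow-fast decomposition.

# oxygen nullcline solved for u at fixed v0 (explicit)
oxygen_nullcline_u <- function(c_, v0, p) {
  num <- c_ * (c_ + p$c3 + p$nu * v0) * (1 + c_) * (c_ + p$c2)
  den <- (c_ + p$c3) * (p$A * (c_ + p$c2) - p$delta * c_ * (1 + c_))
  num / den
}

fast_sub_jacobian <- function(c_, u, v0, p) {
  plankton_jacobian(c(c_, u, v0), p, scaled = FALSE)[1:2, 1:2]
}

# 2-D Newton polish on (F, G) at frozen v0
polish_fast <- function(c_, u, v0, p, maxit = 60L) {
  for (i in seq_len(maxit)) {
    f <- plankton_rhs(c(c_, u, v0), p)[1:2]
    if (max(abs(f)) < 1e-13) break
    d <- tryCatch(solve(fast_sub_jacobian(c_, u, v0, p), -f),
                  error = function(e) NULL)
    if (is.null(d)) return(NULL)
    c_ <- c_ + d[1]; u <- u + d[2]
    if (!is.finite(c_) || !is.finite(u)) return(NULL)
  }
  if (max(abs(plankton_rhs(c(c_, u, v0), p)[1:2])) < 1e-10) c(c_, u) else NULL
}

#' Interior equilibria of the fast oxygen-phytoplankton subsystem
#'
#' For a frozen zooplankton density `v0`, intersects the explicit oxygen
#' nullcline `u(c)` with the phytoplankton balance `G = 0` by a sign-change
#' scan in `c` on `(0, c_max]`, polishes each root by 2-D Newton iteration,
#' and labels 2-D stability from the fast-subsystem Jacobian. The model
#' admits at most two interior fast equilibria; when two exist the lower-u
#' one is a saddle and the upper-u one is stable.
#'
#' @param v0 frozen zooplankton density (>= 0).
#' @param params a [model_params()] object.
#' @param c_max upper end of the oxygen scan range.
#' @param n_scan number of scan points.
#' @return An object of class `"fast_slice"`: `v0` and a data frame
#'   `equilibria` with columns `c, u, stability` sorted by `u`.
#' @export
fast_equilibria <- function(v0, params, c_max = 20, n_scan = 2000L) {
  stopifnot(v0 >= 0)
  p <- params
  cs <- seq(c_max / n_scan, c_max, length.out = n_scan)
  us <- oxygen_nullcline_u(cs, v0, p)
  g <- vapply(seq_along(cs), function(i) {
    if (!is.finite(us[i]) || us[i] <= 0) return(NA_real_)
    plankton_rhs(c(cs[i], us[i], v0), p)[2]
  }, numeric(1))
  roots <- list()
  for (i in seq_len(n_scan - 1L)) {
    if (is.na(g[i]) || is.na(g[i + 1L]) || g[i] * g[i + 1L] >= 0) next
    cu <- polish_fast(mean(cs[i:(i + 1L)]), mean(us[i:(i + 1L)]), v0, p)
    if (is.null(cu) || any(cu <= 1e-10)) next
    dup <- FALSE
    for (q in roots) if (sqrt(sum((q - cu)^2)) < 1e-8) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1L]] <- cu
  }
  if (length(roots)) {
    df <- do.call(rbind, lapply(roots, function(cu) {
      ev <- eigen(fast_sub_jacobian(cu[1], cu[2], v0, p),
                  only.values = TRUE)$values
      stab <- if (all(Re(ev) < 0)) "stable"
      else if (all(Re(ev) > 0)) "unstable" else "saddle"
      data.frame(c = cu[1], u = cu[2], stability = stab)
    }))
    df <- df[order(df$u), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(c = numeric(0), u = numeric(0), stability = character(0))
  }
  structure(list(v0 = v0, equilibria = df), class = "fast_slice")
}

#' Fold point of the fast subsystem
#'
#' Solves `F = 0, G = 0, det(J_sub) = 0` for `(c_s, u_s, v_s)`, where
#' `J_sub` is the 2x2 Jacobian of the fast subsystem: the saddle-node point
#' at which the two interior fast equilibria merge, which is also the fold
#' of the critical manifold of the full system. The Newton iteration is
#' seeded from a bisection in `v0` on the fast-equilibrium count (2 -> 0).
#' The zooplankton reaction `H` is evaluated at the fold with the `mu1`,
#' `mu2` carried by `params` (its sign gives the direction of the slow flow
#' there), and the fold is classified as a jump or canard point via
#' [classify_fold()].
#'
#' @param params a [model_params()] object.
#' @param v0_range range searched for the count transition.
#' @return An object of class `"fold_point"` with elements `c_s, u_s, v_s`,
#'   `H_value`, discriminants `d1, d2`, and `classification`.
#' @examples
#' \donttest{
#' fold_point(model_params(mu1 = 0.3, mu2 = 0.1018, epsilon = 0.5))
#' }
#' @export
fold_point <- function(params, v0_range = c(0, 10)) {
  p <- params
  n_of <- function(v0) nrow(fast_equilibria(v0, p)$equilibria)
  lo <- v0_range[1]; hi <- v0_range[2]
  if (n_of(lo) < 2L) {
    probe <- seq(lo, hi, length.out = 21L)
    k <- which(vapply(probe, n_of, integer(1)) >= 2L)
    if (!length(k))
      stop("no fold: fast subsystem never has two interior equilibria in ",
           "v0 range", call. = FALSE)
    lo <- probe[k[1]]
  }
  if (n_of(hi) >= 2L)
    stop("no fold: two fast equilibria persist at the top of the v0 range",
         call. = FALSE)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (n_of(mid) >= 2L) lo <- mid else hi <- mid
  }
  sl <- fast_equilibria(lo, p)$equilibria      # near-merged pair
  x <- c(mean(sl$c), mean(sl$u), (lo + hi) / 2)
  fv <- function(x) {
    st <- c(x[1], x[2], x[3])
    c(plankton_rhs(st, p)[1:2], det(fast_sub_jacobian(x[1], x[2], x[3], p)))
  }
  for (i in 1:200) {
    f0 <- fv(x)
    if (max(abs(f0)) < 1e-13) break
    J <- matrix(0, 3, 3); hh <- 1e-7
    for (j in 1:3) {
      e <- numeric(3); e[j] <- hh
      J[, j] <- (fv(x + e) - fv(x - e)) / (2 * hh)
    }
    d <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(d)) stop("fold Newton iteration failed", call. = FALSE)
    x <- x + d
  }
  if (max(abs(fv(x))) > 1e-9)
    stop("fold residuals did not converge below 1e-9", call. = FALSE)
  fp <- structure(list(c_s = x[1], u_s = x[2], v_s = x[3],
                       H_value = plankton_H(x, p),
                       d1 = NA_real_, d2 = NA_real_,
                       classification = NA_character_),
                  class = "fold_point")
  classify_fold(fp, p)
}

#' @export
print.fold_point <- function(x, ...) {
  cat(sprintf("fold point: c_s=%.6f u_s=%.6f v_s=%.6f\n",
              x$c_s, x$u_s, x$v_s))
  cat(sprintf("  H = %.6g; d1 = %.4g, d2 = %.4g -> %s point\n",
              x$H_value, x$d1, x$d2, x$classification))
  invisible(x)
}

#' Jump-versus-canard classification of a fold point
#'
#' Evaluates the discriminants `d1 = F_v G_u - F_u G_v` and
#' `d2 = F_v G_c - F_c G_v` from the analytic partial derivatives at the
#' fold. If either is nonzero (above `tol`) the fold is a jump point: the
#' slow trajectory leaves along a fast fiber. Only when both vanish is the
#' fold a canard point, through which trajectories can follow the
#' repelling branch for O(1) slow time.
#'
#' @param fold a `"fold_point"`.
#' @param params a [model_params()] object.
#' @param tol discriminant tolerance.
#' @return The `"fold_point"` with `d1`, `d2` and `classification` filled.
#' @export
classify_fold <- function(fold, params, tol = 1e-6) {
  stopifnot(inherits(fold, "fold_point"))
  st <- c(fold$c_s, fold$u_s, fold$v_s)
  J <- plankton_jacobian(st, params, scaled = FALSE)
  Fc <- J[1, 1]; Fu <- J[1, 2]; Fv <- J[1, 3]
  Gc <- J[2, 1]; Gu <- J[2, 2]; Gv <- J[2, 3]
  fold$d1 <- Fv * Gu - Fu * Gv
  fold$d2 <- Fv * Gc - Fc * Gv
  fold$classification <-
    if (abs(fold$d1) < tol && abs(fold$d2) < tol) "canard" else "jump"
  fold
}

#' Critical manifold of the slow-fast decomposition
#'
#' Collects the interior equilibria of the fast subsystem over a grid of
#' frozen zooplankton densities. Samples with `u > u_s` form the attracting
#' branch, samples with `u < u_s` the repelling branch; the two branches
#' meet at the fold. The trivial branch (the extinction line `c = u = 0`)
#' is recorded with its eigenvalues `-1 - nu v / c3` and `-v/h - sigma`,
#' both negative for all `v >= 0`.
#'
#' @param params a [model_params()] object.
#' @param v0_grid zooplankton grid; by default 400 uniform points on
#'   `[0, 1.1 v_s]` with a 10-fold denser refinement over the final 5%
#'   before the fold, where the branches converge.
#' @return An object of class `"critical_manifold"`: data frame `samples`
#'   (`v0, c, u, branch`), the `fold` point, and `trivial` (eigenvalues of
#'   the extinction line at the sampled `v`).
#' @export
build_manifold <- function(params, v0_grid = NULL) {
  p <- params
  fp <- fold_point(p)
  if (is.null(v0_grid)) {
    v_hi <- 1.1 * fp$v_s
    coarse <- seq(0, 0.95 * fp$v_s, length.out = 360L)
    fine <- seq(0.95 * fp$v_s, fp$v_s, length.out = 400L)
    v0_grid <- sort(unique(c(coarse, fine, seq(fp$v_s, v_hi, length.out = 40L))))
  }
  rows <- list()
  for (v0 in v0_grid) {
    sl <- fast_equilibria(v0, p)$equilibria
    if (!nrow(sl)) next
    for (i in seq_len(nrow(sl))) {
      rows[[length(rows) + 1L]] <-
        data.frame(v0 = v0, c = sl$c[i], u = sl$u[i],
                   branch = if (sl$u[i] > fp$u_s) "attracting" else "repelling")
    }
  }
  samples <- do.call(rbind, rows)
  trivial <- data.frame(v = v0_grid,
                        lambda1 = -1 - p$nu * v0_grid / p$c3,
                        lambda2 = -v0_grid / p$h - p$sigma)
  structure(list(samples = samples, fold = fp, trivial = trivial),
            class = "critical_manifold")
}

#' @rdname build_manifold
#' @param x a `"critical_manifold"`.
#' @param path CSV output path (columns `v0, c, u, branch`).
#' @export
write_manifold_csv <- function(x, path) {
  utils::write.csv(x$samples, path, row.names = FALSE)
  invisible(path)
}

#' Reduced (slow) flow on the critical manifold
#'
#' Differentiating `F = 0` and `G = 0` implicitly along the manifold gives
#' the slow dynamics
#' `dc/dtau = -(F_v G_u - F_u G_v)/(F_c G_u - F_u G_c) H`,
#' `du/dtau = -(F_v G_c - F_c G_v)/(G_c F_u - G_u F_c) H`,
#' `dv/dtau = H`. The flow is singular where `F_c G_u - F_u G_c = 0`, which
#' happens exactly at the fold: the reduced solution blows up there.
#'
#' @param point numeric `c(c, u, v)` on the manifold (`|F|, |G| <= 1e-8`).
#' @param params a [model_params()] object.
#' @return Numeric `c(dc, du, dv)` in slow time.
#' @export
slow_flow <- function(point, params) {
  f <- plankton_rhs(point, params)[1:2]
  if (max(abs(f)) > 1e-8)
    stop("point is not on the critical manifold (|F| or |G| > 1e-8)",
         call. = FALSE)
  J <- plankton_jacobian(point, params, scaled = FALSE)
  Fc <- J[1, 1]; Fu <- J[1, 2]; Fv <- J[1, 3]
  Gc <- J[2, 1]; Gu <- J[2, 2]; Gv <- J[2, 3]
  den <- Fc * Gu - Fu * Gc
  if (abs(den) < 1e-10)
    stop("slow flow singular: fold point (F_c G_u - F_u G_c = 0)",
         call. = FALSE)
  H <- plankton_H(point, params)
  c(dc = -(Fv * Gu - Fu * Gv) / den * H,
    du = -(Fv * Gc - Fc * Gv) / (-den) * H,
    dv = H)
}
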