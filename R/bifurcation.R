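# One-parameter bifurcation analysis in mu1 or mu2.

#' Integrate the plankton-oxygen model
#'
#' Thin wrapper around [deSolve::ode()] (lsoda) for the fast-time system
#' `(dc/dt, du/dt, dv/dt) = (F, G, epsilon H)`. Tight default tolerances:
#' slow-fast trajectories near the repelling branch of the critical
#' manifold are sensitive to integration error.
#'
#' @param params a [model_params()] object.
#' @param y0 initial state `c(c, u, v)`.
#' @param times output times (numeric vector).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param method integration method passed to [deSolve::ode()].
#' @return The `deSolve` output matrix (columns `time, c, u, v`).
#' @export
integrate_model <- function(params, y0, times, rtol = 1e-9, atol = 1e-11,
                            method = "lsoda") {
  f <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(plankton_rhs(y, params))
  }
  out <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 100000)
  colnames(out) <- c("time", "c", "u", "v")
  out
}

set_param <- function(params, vary, value) {
  params[[vary]] <- value
  validate_params(params)
  params
}

# Equilibrium tracker: finds the coexistence state at a parameter value,
# seeded from the nearest previously visited value (natural-parameter
# continuation); falls back to the multi-start grid search.
make_eq_tracker <- function(params, vary, branch = "upper") {
  cache <- list()   # list of list(val =, coords =)
  function(value) {
    p <- set_param(params, vary, value)
    if (length(cache)) {
      d <- vapply(cache, function(z) abs(z$val - value), numeric(1))
      s <- newton_fgh(cache[[which.min(d)]]$coords, p)
      if (!is.null(s) && all(s > 1e-10)) {
        cache[[length(cache) + 1L]] <<- list(val = value, coords = s)
        return(s)
      }
    }
    eqs <- find_coexistence(p)
    if (!length(eqs)) return(NULL)
    cs <- vapply(eqs, function(e) e$coords[1], numeric(1))
    coords <- eqs[[if (branch == "upper") which.max(cs) else which.min(cs)]]$coords
    cache[[length(cache) + 1L]] <<- list(val = value, coords = coords)
    coords
  }
}

hopf_test_value <- function(coords, params) {
  rh <- char_poly_coeffs(plankton_jacobian(coords, params))
  rh[["p1"]] * rh[["p2"]] - rh[["p0"]]
}

#' Hopf bifurcation threshold
#'
#' Locates the Hopf bifurcation of the coexistence equilibrium along a
#' one-parameter family in `mu1` or `mu2`, by bisecting the Routh--Hurwitz
#' test function `p1 p2 - p0` (which vanishes where the complex eigenvalue
#' pair crosses the imaginary axis) along the continued equilibrium branch.
#' The epsilon-scaled Jacobian is used throughout, so the threshold depends
#' on the timescale separation (a singular Hopf point for small `epsilon`).
#'
#' @param params a [model_params()] object (values of the non-varied
#'   parameters).
#' @param vary `"mu1"` or `"mu2"`.
#' @param bracket length-2 numeric; the test function must change sign
#'   between the ends.
#' @param branch which coexistence branch to follow when two exist
#'   (`"upper"` = larger oxygen component; the non-saddle branch).
#' @param tol parameter tolerance of the bisection.
#' @return An object of class `"hopf_point"`: the threshold, the imaginary
#'   part `omega` of the critical pair, the equilibrium coordinates there,
#'   and (once [first_lyapunov()] has been applied) the Lyapunov
#'   coefficient and criticality.
#' @examples
#' \donttest{
#' p <- model_params(mu1 = 0.05, mu2 = 0.4, epsilon = 1)
#' hopf_threshold(p, "mu2", c(0.3, 0.45))  # threshold 0.35405
#' }
#' @export
hopf_threshold <- function(params, vary = c("mu2", "mu1"), bracket,
                           branch = "upper", tol = 1e-7) {
  vary <- match.arg(vary)
  track <- make_eq_tracker(params, vary, branch)
  tf <- function(m) {
    e <- track(m)
    if (is.null(e))
      stop("equilibrium branch lost inside bracket at ", vary, " = ", m,
           call. = FALSE)
    hopf_test_value(e, set_param(params, vary, m))
  }
  flo <- tf(bracket[1]); fhi <- tf(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no Hopf in bracket: test function does not change sign",
         call. = FALSE)
  r <- stats::uniroot(tf, bracket, f.lower = flo, f.upper = fhi, tol = tol)
  thr <- r$root
  p_at <- set_param(params, vary, thr)
  coords <- track(thr)
  rh <- char_poly_coeffs(plankton_jacobian(coords, p_at))
  if (!(rh[["p0"]] > 0 && rh[["p2"]] > 0))
    stop("p0 > 0, p2 > 0 fails at the root: not a Hopf point", call. = FALSE)
  ev <- eigen(plankton_jacobian(coords, p_at), only.values = TRUE)$values
  ip <- which(Im(ev) > 0)
  omega <- if (length(ip)) Im(ev[ip[1]]) else sqrt(max(rh[["p1"]], 0))
  structure(list(varied_parameter = vary, threshold = thr, omega = omega,
                 equilibrium = coords, l1 = NA_real_,
                 criticality = NA_character_, params = p_at),
            class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  cat(sprintf("Hopf point: %s = %.7g, omega = %.5g\n",
              x$varied_parameter, x$threshold, x$omega))
  if (!is.na(x$l1))
    cat(sprintf("  first Lyapunov coefficient l1 = %.5g (%s)\n",
                x$l1, x$criticality))
  invisible(x)
}

#' First Lyapunov coefficient at a Hopf point
#'
#' Computes the first Lyapunov coefficient by the standard projection
#' (normal-form) method for n-dimensional systems: with `A q = i w q`,
#' `A' p = -i w p`, `<p, q> = 1`, and `B`, `C` the bilinear and trilinear
#' forms of the Taylor expansion at the equilibrium,
#' `l1 = Re(<p, C(q,q,conj(q))> - 2 <p, B(q, A^-1 B(q, conj(q)))> +
#'         <p, B(conj(q), (2 i w I - A)^-1 B(q, q))>) / (2 w)`.
#' The derivative tensors are obtained by central finite differences of the
#' analytic Jacobian. The sign determines criticality (`l1 < 0`:
#' supercritical, stable cycle; `l1 > 0`: subcritical); the magnitude is
#' normalization-dependent and should be read with that caveat.
#'
#' @param hopf a `"hopf_point"` from [hopf_threshold()].
#' @param fd_step finite-difference step for the derivative tensors.
#' @return The `"hopf_point"` with `l1` and `criticality` filled in.
#' @export
first_lyapunov <- function(hopf, fd_step = 1e-4) {
  stopifnot(inherits(hopf, "hopf_point"))
  p <- hopf$params
  x <- hopf$equilibrium
  A <- plankton_jacobian(x, p)
  ev <- eigen(A)
  ip <- which(Im(ev$values) > 1e-8)
  if (!length(ip) || abs(hopf$omega) < 1e-8)
    stop("degenerate Hopf: omega ~ 0 (fold-Hopf interaction)", call. = FALSE)
  i1 <- ip[1]
  omega <- Im(ev$values[i1])
  q <- ev$vectors[, i1]
  evl <- eigen(t(A))
  i2 <- which.min(abs(evl$values - (-1i * omega)))
  pp <- evl$vectors[, i2]
  pp <- pp / Conj(sum(Conj(pp) * q))    # <p, q> = sum(conj(p) q) = 1
  h <- fd_step
  Jf <- function(y) plankton_jacobian(y, p)
  B2 <- array(0, c(3, 3, 3)); C3 <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) {
    e <- numeric(3); e[k] <- h
    B2[, , k] <- (Jf(x + e) - Jf(x - e)) / (2 * h)
  }
  for (k in 1:3) for (l in 1:3) {
    ek <- numeric(3); ek[k] <- h; el <- numeric(3); el[l] <- h
    C3[, , k, l] <- (Jf(x + ek + el) - Jf(x + ek - el) -
                       Jf(x - ek + el) + Jf(x - ek - el)) / (4 * h^2)
  }
  Bf <- function(a, b)
    vapply(1:3, function(i) sum(B2[i, , ] * outer(a, b)), complex(1))
  Cf <- function(a, b, cc)
    vapply(1:3, function(i) {
      s <- 0 + 0i
      for (j in 1:3) for (k in 1:3) for (l in 1:3)
        s <- s + C3[i, j, k, l] * a[j] * b[k] * cc[l]
      s
    }, complex(1))
  qb <- Conj(q)
  t1 <- sum(Conj(pp) * Cf(q, q, qb))
  t2 <- -2 * sum(Conj(pp) * Bf(q, solve(A, Bf(q, qb))))
  t3 <- sum(Conj(pp) * Bf(qb, solve(2i * omega * diag(3) - A, Bf(q, q))))
  l1 <- Re(t1 + t2 + t3) / (2 * omega)
  hopf$l1 <- l1
  hopf$criticality <- if (l1 < 0) "supercritical" else "subcritical"
  hopf
}

# envelope of the oxygen component over a long integration; doubles the
# recording window until the peak amplitude has converged (drift < 1%)
cycle_envelope <- function(params, coords, t_transient = 2000,
                           t_record = 1000, offset = 0.01) {
  y0 <- coords + offset
  out <- integrate_model(params, y0, c(0, t_transient))
  y1 <- pmax(out[nrow(out), 2:4], 0)
  if (y1[2] < 1e-6)   # collapsed during the transient
    return(list(collapsed = TRUE, cycle_min = NA_real_, cycle_max = NA_real_))
  env <- NULL
  for (rep in 1:3) {
    tt <- seq(0, t_record, by = 0.5)
    out <- integrate_model(params, y1, tt)
    cmin <- min(out[, "c"]); cmax <- max(out[, "c"])
    if (out[nrow(out), "u"] < 1e-6)
      return(list(collapsed = TRUE, cycle_min = NA_real_, cycle_max = NA_real_))
    half <- out[out[, "time"] > t_record / 2, "c"]
    drift <- abs((max(half) - min(half)) - (cmax - cmin)) /
      max(cmax - cmin, 1e-12)
    env <- list(collapsed = FALSE, cycle_min = cmin, cycle_max = cmax)
    if (cmax - cmin < 1e-6 || drift < 0.01) break
    y1 <- pmax(out[nrow(out), 2:4], 0)
    t_record <- 2 * t_record
  }
  env
}

#' One-parameter bifurcation diagram
#'
#' Continues the coexistence equilibrium over a parameter grid
#' (Newton-seeded from the previous grid point) and, wherever the
#' equilibrium is unstable, records the envelope (min/max of the oxygen
#' component) of the attractor reached from a small perturbation of the
#' equilibrium: a transient of `t_transient` time units is discarded and
#' extrema are collected over `t_record` units (doubled automatically if
#' the envelope has not converged). Collapse to the extinction state is
#' recorded explicitly.
#'
#' @inheritParams hopf_threshold
#' @param grid sorted numeric vector of parameter values.
#' @param cycles logical; integrate for cycle envelopes at unstable points.
#' @param t_transient,t_record transient and recording times.
#' @return A data frame of class `"bifurcation_branch"` with columns
#'   `parameter, c_eq, u_eq, v_eq, stability, cycle_min, cycle_max,
#'   collapsed`.
#' @export
branch_diagram <- function(params, vary = c("mu2", "mu1"), grid,
                           branch = "upper", cycles = TRUE,
                           t_transient = 2000, t_record = 1000) {
  vary <- match.arg(vary)
  grid <- sort(grid)
  track <- make_eq_tracker(params, vary, branch)
  rows <- list()
  for (m in grid) {
    p <- set_param(params, vary, m)
    coords <- track(m)
    if (is.null(coords)) break        # branch terminated (candidate fold)
    eq <- classify_or_marginal(coords, p, "coexistence")
    row <- data.frame(parameter = m, c_eq = coords[1], u_eq = coords[2],
                      v_eq = coords[3], stability = eq$stability,
                      cycle_min = NA_real_, cycle_max = NA_real_,
                      collapsed = FALSE)
    if (cycles && eq$stability != "stable") {
      env <- cycle_envelope(p, coords, t_transient, t_record)
      row$collapsed <- env$collapsed
      if (!env$collapsed && env$cycle_max - env$cycle_min > 1e-6) {
        row$cycle_min <- env$cycle_min
        row$cycle_max <- env$cycle_max
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "vary") <- vary
  class(out) <- c("bifurcation_branch", class(out))
  out
}

#' @rdname branch_diagram
#' @param x a `"bifurcation_branch"`.
#' @param path CSV output path.
#' @export
write_branch_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# did the trajectory collapse? u < 1e-6 sustained over the last `hold`
# time units of the run
run_collapses <- function(params, y0, t_max = 5000, hold = 50) {
  tt <- c(seq(0, t_max - hold, length.out = 201), seq(t_max - hold, t_max, by = 5))
  out <- integrate_model(params, y0, tt)
  tail_u <- out[out[, "time"] >= t_max - hold, "u"]
  all(tail_u < 1e-6)
}

#' Extinction (system-collapse) threshold by simulation bisection
#'
#' Operational detection of global bifurcations (heteroclinic destruction
#' of the stable cycle, canard-cycle blow-up): the standard run starts at
#' the coexistence equilibrium perturbed by `ic_offset` and integrates to
#' `t_max`; the outcome is "collapse" if the phytoplankton density stays
#' below `1e-6` over the final 50 time units, else "sustained". The varied
#' parameter is bisected on this binary outcome.
#'
#' @inheritParams hopf_threshold
#' @param ic_offset added to each equilibrium coordinate for the initial
#'   condition.
#' @param t_max integration horizon per run.
#' @param tol parameter tolerance of the bisection.
#' @return The threshold parameter value.
#' @export
extinction_threshold <- function(params, vary = c("mu2", "mu1"), bracket,
                                 ic_offset = 0.01, t_max = 5000,
                                 branch = "upper", tol = 1e-5) {
  vary <- match.arg(vary)
  track <- make_eq_tracker(params, vary, branch)
  outcome <- function(m) {
    p <- set_param(params, vary, m)
    e <- track(m)
    if (is.null(e)) return(TRUE)     # no coexistence state: collapse regime
    run_collapses(p, e + ic_offset, t_max = t_max)
  }
  lo <- bracket[1]; hi <- bracket[2]
  olo <- outcome(lo); ohi <- outcome(hi)
  if (olo == ohi)
    stop("no threshold in bracket: same outcome at both ends", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (outcome(mid) == olo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
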