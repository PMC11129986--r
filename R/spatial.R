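# 1-D reaction-diffusion simulator: the explicit scheme used throughout
# the spatial analyses (forward Euler in time, 3-point central differences
# for diffusion, zero-flux boundaries), plus initial-condition builders,
# OMZ detection and regime classification.

#' Uniform 1-D spatial grid
#'
#' @param L domain length (default 500).
#' @param dx node spacing (default 1); nodes sit at `x = 0, dx, ..., L`.
#' @return An object of class `"grid1d"` with `L, dx, n, x`.
#' @export
grid1d <- function(L = 500, dx = 1) {
  stopifnot(L > 0, dx > 0)
  n <- as.integer(round(L / dx)) + 1L
  if (abs((n - 1L) * dx - L) > 1e-9)
    stop("L must be an integer multiple of dx", call. = FALSE)
  if (n < 16L) stop("grid too coarse: need at least 16 nodes", call. = FALSE)
  structure(list(L = L, dx = dx, n = n, x = seq(0, L, by = dx)),
            class = "grid1d")
}

#' Initial fields: localized perturbation of the homogeneous state
#'
#' Builds the three fields at `t = 0` as the coexistence steady state
#' perturbed inside a central window `|x - L/2| < half_width`. The
#' `"standard"` variant raises oxygen by 0.1 and phytoplankton by 0.2
#' there; the `"depleted"` variant lowers them by 0.5 and 0.2 (an initial
#' oxygen deficit). Zooplankton starts uniform at its steady-state value.
#'
#' @param grid a [grid1d()] object.
#' @param equilibrium coexistence `"equilibrium"` or coordinates `c(c,u,v)`.
#' @param variant `"standard"` or `"depleted"`.
#' @param half_width half-width of the perturbed window (strict inequality).
#' @return An object of class `"field_state"`: `x, c, u, v, time`.
#' @export
make_initial <- function(grid, equilibrium,
                         variant = c("standard", "depleted"),
                         half_width = 10) {
  variant <- match.arg(variant)
  e <- eq_coords(equilibrium)
  w <- abs(grid$x - grid$L / 2) < half_width
  cc <- rep(e[1], grid$n); u <- rep(e[2], grid$n); v <- rep(e[3], grid$n)
  if (variant == "standard") {
    cc[w] <- e[1] + 0.1
    u[w] <- e[2] + 0.2
  } else {
    if (e[1] < 0.5)
      stop("depleted variant needs c* >= 0.5 (initial oxygen would be negative)",
           call. = FALSE)
    cc[w] <- e[1] - 0.5
    u[w] <- e[2] - 0.2
  }
  structure(list(x = grid$x, c = cc, u = u, v = v, time = 0,
                 grid = grid), class = "field_state")
}

check_cfl <- function(D, dt, dx) {
  if (max(1, D) * dt / dx^2 > 0.5)
    stop("explicit-scheme stability constraint violated: need ",
         "max(1, D) * dt / dx^2 <= 0.5", call. = FALSE)
  invisible(TRUE)
}

#' Single explicit time step (reference implementation)
#'
#' One forward-Euler update of the reaction-diffusion system: 3-point
#' Laplacian with mirrored ghost nodes (zero flux), reaction terms from
#' [plankton_rhs()], diffusivities `(1, 1, D)`. The long-run integrator
#' [simulate_rd()] applies exactly this update in compiled code; this R
#' version exists for step-level verification.
#'
#' @param field a `"field_state"`.
#' @param params a [model_params()] object.
#' @param D zooplankton diffusivity ratio.
#' @param dt time step (must satisfy `max(1, D) dt / dx^2 <= 0.5`).
#' @param reaction logical; set `FALSE` for the pure-diffusion limit (the
#'   reaction terms are dropped), in which the scheme conserves the
#'   trapezoid-weighted mass of each field exactly.
#' @return The updated `"field_state"`.
#' @export
rd_step <- function(field, params, D, dt, reaction = TRUE) {
  g <- field$grid
  check_cfl(D, dt, g$dx)
  lap <- function(z) {
    n <- length(z)
    (c(z[2], z[-n]) - 2 * z + c(z[-1], z[n - 1])) / g$dx^2
  }
  p <- params
  cc <- field$c; u <- field$u; v <- field$v
  Fr <- p$A * u / (cc + 1) - p$delta * u * cc / (cc + p$c2) -
    p$nu * cc * v / (cc + p$c3) - cc
  Gr <- (p$B * cc / (cc + p$c1) - u) * u - u * v / (u + p$h) - p$sigma * u
  Hr <- p$eta * cc^2 / (cc^2 + p$c4^2) * u * v / (u + p$h) -
    p$mu1 * v - p$mu2 * v^2
  if (!reaction) Fr <- Gr <- Hr <- 0
  cc <- cc + dt * (lap(field$c) + Fr)
  u <- u + dt * (lap(field$u) + Gr)
  v <- v + dt * (D * lap(field$v) + p$epsilon * Hr)
  worst <- min(cc, u, v)
  if (worst < -1e-8)
    stop("numerical failure: field value below -1e-8", call. = FALSE)
  clamped <- sum(cc < 0) + sum(u < 0) + sum(v < 0)
  cc[cc < 0] <- 0; u[u < 0] <- 0; v[v < 0] <- 0
  out <- field
  out$c <- cc; out$u <- u; out$v <- v
  out$time <- field$time + dt
  attr(out, "clamped") <- clamped
  out
}

#' Simulate the 1-D reaction-diffusion system
#'
#' Full run of the explicit scheme (compiled core), storing field
#' snapshots every `save_every` time units together with the
#' spatial-average series of all three fields. Deterministic: no random
#' numbers are used anywhere; reruns with the same configuration are
#' bitwise identical.
#'
#' @param params a [model_params()] object.
#' @param D zooplankton diffusivity ratio.
#' @param grid a [grid1d()] object.
#' @param dt time step (default 0.01).
#' @param T_end final time.
#' @param ic_variant initial-condition variant for [make_initial()], used
#'   when `init` is not supplied.
#' @param save_every snapshot cadence in time units.
#' @param equilibrium optional coexistence state; computed via
#'   [find_coexistence()] (temporally relevant branch = largest oxygen
#'   component) when missing.
#' @param init optional `"field_state"` overriding the built initial
#'   condition.
#' @return An object of class `"simulation_output"`: snapshot `times`,
#'   matrices `c, u, v` (snapshots in rows), `avg` (spatial means per
#'   snapshot), the grid, and run metadata.
#' @export
simulate_rd <- function(params, D, grid = grid1d(), dt = 0.01, T_end = 5000,
                        ic_variant = "standard", save_every = 10,
                        equilibrium = NULL, init = NULL) {
  check_cfl(D, dt, grid$dx)
  stopifnot(T_end > 0)
  if (is.null(init)) {
    if (is.null(equilibrium)) {
      eqs <- find_coexistence(params)
      if (!length(eqs)) stop("no coexistence state for these parameters",
                             call. = FALSE)
      equilibrium <- eqs[[length(eqs)]]
    }
    init <- make_initial(grid, equilibrium, ic_variant)
  }
  sav <- max(1L, round(save_every / dt))
  nsteps <- round(T_end / dt)
  nsteps <- (nsteps %/% sav) * sav
  raw <- rd_simulate_cpp(init$c, init$u, init$v, unclass(params)[
    c("A", "B", "sigma", "c1", "c2", "c3", "c4", "eta", "delta", "nu", "h",
      "mu1", "mu2", "epsilon")], D, grid$dx, dt, nsteps, sav)
  avg <- data.frame(time = raw$times,
                    c = rowMeans(raw$c), u = rowMeans(raw$u),
                    v = rowMeans(raw$v))
  structure(list(times = raw$times, x = grid$x,
                 c = raw$c, u = raw$u, v = raw$v, avg = avg, grid = grid,
                 params = params, D = D, dt = dt,
                 equilibrium = if (!is.null(equilibrium)) eq_coords(equilibrium),
                 clamped = raw$clamped),
            class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  cat(sprintf("reaction-diffusion run: L=%g dx=%g dt=%g, %d snapshots to t=%g\n",
              x$grid$L, x$grid$dx, x$dt, length(x$times), max(x$times)))
  cat(sprintf("  D=%g epsilon=%g mu1=%g mu2=%g; final <c>=%.4g <u>=%.4g <v>=%.4g\n",
              x$D, x$params$epsilon, x$params$mu1, x$params$mu2,
              utils::tail(x$avg$c, 1), utils::tail(x$avg$u, 1),
              utils::tail(x$avg$v, 1)))
  invisible(x)
}

#' @rdname simulate_rd
#' @param x a `"simulation_output"`.
#' @param path CSV output path for the spatial-average series.
#' @export
write_averages_csv <- function(x, path) {
  utils::write.csv(x$avg, path, row.names = FALSE)
  invisible(path)
}

#' Detect oxygen minimum zones in a field
#'
#' Maximal runs of at least two consecutive nodes whose oxygen
#' concentration falls below `theta * c_star` are reported as OMZ
#' intervals.
#'
#' @param field a `"field_state"`, a `"simulation_output"` (final snapshot
#'   used), or a numeric oxygen profile.
#' @param c_star reference (steady-state) oxygen concentration.
#' @param theta threshold fraction in (0, 1); default 0.5.
#' @param x optional node coordinates when `field` is a bare numeric.
#' @return An object of class `"omz_report"`: data frame `intervals`
#'   (`x_start, x_end, width`), `theta`, `c_star`.
#' @export
detect_omz <- function(field, c_star, theta = 0.5, x = NULL) {
  stopifnot(c_star > 0, theta > 0, theta < 1)
  if (inherits(field, "simulation_output")) {
    cc <- field$c[nrow(field$c), ]; x <- field$x
  } else if (inherits(field, "field_state")) {
    cc <- field$c; x <- field$x
  } else {
    cc <- as.numeric(field)
    if (is.null(x)) x <- seq_along(cc) - 1
  }
  low <- cc < theta * c_star
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  intervals <- data.frame(x_start = x[starts[keep]], x_end = x[ends[keep]])
  intervals$width <- intervals$x_end - intervals$x_start
  structure(list(intervals = intervals, theta = theta, c_star = c_star),
            class = "omz_report")
}

#' @export
print.omz_report <- function(x, ...) {
  if (!nrow(x$intervals)) {
    cat(sprintf("no OMZ (threshold %.3g = %.2g x c*)\n",
                x$theta * x$c_star, x$theta))
  } else {
    cat(sprintf("%d OMZ interval(s) below %.2g x c*:\n",
                nrow(x$intervals), x$theta))
    print(x$intervals)
  }
  invisible(x)
}

#' Classify the large-time regime of a spatial run
#'
#' Decision tree over the final classification window (default 500 time
#' units of snapshots):
#' `global_anoxia` if the final mean oxygen is below 0.01;
#' `homogeneous_steady` if the final snapshot is spatially flat (relative
#' spatial sd of oxygen below 1e-4) and the mean-oxygen series is
#' temporally flat over the window; `stationary_pattern` if the final
#' snapshot is strongly structured (relative spatial sd at least 1e-2)
#' and frozen (rms change per node between the last two snapshots below
#' 1e-4); `localized_oscillation` if temporal variability is confined to
#' under 20% of the nodes; otherwise `dynamic_irregular`.
#'
#' @param output a `"simulation_output"`; the run must cover at least
#'   twice the window.
#' @param window classification window in time units (default 500).
#' @return One of `"homogeneous_steady"`, `"localized_oscillation"`,
#'   `"stationary_pattern"`, `"dynamic_irregular"`, `"global_anoxia"`.
#' @export
classify_regime <- function(output, window = 500) {
  stopifnot(inherits(output, "simulation_output"))
  t_end <- max(output$times)
  if (t_end < 2 * window)
    stop("run too short to classify: need T >= 2 x window", call. = FALSE)
  iw <- which(output$times >= t_end - window)
  cfin <- output$c[nrow(output$c), ]
  cprev <- output$c[nrow(output$c) - 1L, ]
  mfin <- mean(cfin)
  if (mfin < 0.01) return("global_anoxia")
  rel_sp_sd <- stats::sd(cfin) / mfin
  avg_w <- output$avg$c[iw]
  rel_t_sd <- stats::sd(avg_w) / mean(avg_w)
  if (rel_sp_sd < 1e-4 && rel_t_sd < 1e-4) return("homogeneous_steady")
  rms_change <- sqrt(mean((cfin - cprev)^2))
  if (rel_sp_sd >= 1e-2 && rms_change < 1e-4) return("stationary_pattern")
  node_sd <- apply(output$c[iw, , drop = FALSE], 2, stats::sd)
  osc_frac <- mean(node_sd > 1e-3 * mean(output$c[iw, ]))
  if (osc_frac < 0.2) return("localized_oscillation")
  "dynamic_irregular"
}

#' Dominant spatial mode of the final snapshot
#'
#' Discrete Fourier analysis of the mean-removed final oxygen profile;
#' used to compare an emergent stationary pattern with the critical Turing
#' wavenumber.
#'
#' @param output a `"simulation_output"`.
#' @return A list with the dominant wavenumber `k` and the grid mode
#'   spacing `dk = 2 pi / (n dx)`.
#' @export
dominant_mode <- function(output) {
  cc <- output$c[nrow(output$c), ]
  z <- cc - mean(cc)
  n <- length(z)
  sp <- Mod(stats::fft(z))[2:floor(n / 2)]
  k_idx <- which.max(sp)
  dk <- 2 * pi / (n * output$grid$dx)
  list(k = k_idx * dk, dk = dk)
}
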