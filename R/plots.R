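# Presentation-only plotting (base graphics); nothing here is load-bearing.

#' @export
plot.simulation_output <- function(x, field = c("c", "u", "v"), ...) {
  field <- match.arg(field)
  z <- x[[field]]
  graphics::image(x = x$times, y = x$x, z = z,
                  xlab = "time", ylab = "x",
                  main = sprintf("space-time %s field", field),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' @export
plot.bifurcation_branch <- function(x, ...) {
  vary <- attr(x, "vary")
  ylim <- range(c(x$c_eq, x$cycle_min, x$cycle_max), na.rm = TRUE)
  graphics::plot(x$parameter, x$c_eq, type = "n", xlab = vary,
                 ylab = "oxygen component c", ylim = ylim, ...)
  st <- x$stability == "stable"
  graphics::lines(x$parameter[st], x$c_eq[st], col = "blue", lwd = 2)
  graphics::lines(x$parameter[!st], x$c_eq[!st], col = "red", lty = 2)
  ok <- is.finite(x$cycle_min)
  if (any(ok)) {
    graphics::lines(x$parameter[ok], x$cycle_min[ok], col = "blue")
    graphics::lines(x$parameter[ok], x$cycle_max[ok], col = "blue")
  }
  invisible(x)
}

#' @export
plot.dispersion_data <- function(x, ...) {
  graphics::plot(x$k2_grid, x$p0, type = "l", log = "x",
                 xlab = expression(k^2), ylab = expression(p[0](k^2)), ...)
  graphics::abline(h = 0, col = "grey")
  if (is.finite(x$kT2))
    graphics::abline(v = x$kT2, col = "red", lty = 2)
  invisible(x)
}

#' @export
plot.critical_manifold <- function(x, ...) {
  s <- x$samples
  graphics::plot(s$v0, s$u, type = "n", xlab = "v (frozen)", ylab = "u", ...)
  att <- s$branch == "attracting"
  graphics::points(s$v0[att], s$u[att], pch = 16, cex = 0.3, col = "blue")
  graphics::points(s$v0[!att], s$u[!att], pch = 16, cex = 0.3, col = "red")
  graphics::points(x$fold$v_s, x$fold$u_s, pch = 19, col = "black")
  invisible(x)
}
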