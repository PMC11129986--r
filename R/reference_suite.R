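# Reference-value suite and run configuration round-trip.

#' Run the built-in reference-value suite
#'
#' Recomputes, from scratch, the twelve benchmark quantities of the
#' baseline analysis -- the two zooplankton-free oxygen levels, the fold
#' point and the zooplankton reaction evaluated there, six Hopf thresholds
#' across mortality/timescale combinations, the critical Turing wavenumber,
#' and the upper end of the instability window of the oxygen-rich
#' zooplankton-free state -- and compares each against its reference value
#' at the stated tolerance. Every value is computed by the package's own
#' solvers at call time; the suite is deterministic, so reruns are
#' identical.
#'
#' @param outdir optional directory; when given, writes
#'   `reference_suite.json` and a human-readable `reference_suite.txt`.
#' @return A data frame with columns
#'   `id, description, computed, expected, tol, pass` (12 rows). Errors in
#'   individual computations are captured per row, not propagated.
#' @export
run_reference_suite <- function(outdir = NULL) {
  base <- function(mu1, mu2, eps) model_params(mu1 = mu1, mu2 = mu2,
                                               epsilon = eps)
  items <- list(
    list(id = "t1", desc = "zooplankton-free state, lower oxygen level",
         expected = 0.0258, tol = 1e-3,
         fun = function() find_zooplankton_free(base(0.1, 0.1, 1))[[1]]$coords[1]),
    list(id = "t2", desc = "zooplankton-free state, upper oxygen level",
         expected = 1.712, tol = 1e-3,
         fun = function() find_zooplankton_free(base(0.1, 0.1, 1))[[2]]$coords[1]),
    list(id = "t3", desc = "fold point of the fast subsystem, c_s",
         expected = 1.26531, tol = 1e-4,
         fun = function() fold_point(base(0.3, 0.1018, 0.5))$c_s),
    list(id = "t4", desc = "zooplankton reaction H at the fold (mu1=0.3, mu2=0.1018)",
         expected = 0.001859, tol = 1e-5,
         fun = function() fold_point(base(0.3, 0.1018, 0.5))$H_value),
    list(id = "t5", desc = "Hopf threshold in mu2 (mu1=0.05, eps=1)",
         expected = 0.35405, tol = 1e-3,
         fun = function() hopf_threshold(base(0.05, 0.4, 1), "mu2",
                                         c(0.3, 0.45))$threshold),
    list(id = "t6", desc = "Hopf threshold in mu1 (mu2=0, eps=1)",
         expected = 0.398, tol = 2e-3,
         fun = function() hopf_threshold(base(0.3, 0, 1), "mu1",
                                         c(0.3, 0.45))$threshold),
    list(id = "t7", desc = "Hopf threshold in mu2 (mu1=0, eps=1, upper branch)",
         expected = 0.408, tol = 2e-3,
         fun = function() hopf_threshold(base(0, 0.42, 1), "mu2",
                                         c(0.39, 0.45))$threshold),
    list(id = "t8", desc = "Hopf threshold in mu2 (mu1=0.24, eps=1)",
         expected = 0.1577, tol = 2e-3,
         fun = function() hopf_threshold(base(0.24, 0.2, 1), "mu2",
                                         c(0.13, 0.25))$threshold),
    list(id = "t9", desc = "singular Hopf threshold in mu2 (mu1=0.24, eps=0.5)",
         expected = 0.1638, tol = 2e-3,
         fun = function() hopf_threshold(base(0.24, 0.2, 0.5), "mu2",
                                         c(0.13, 0.25))$threshold),
    list(id = "t10", desc = "singular Hopf threshold in mu2 (mu1=0.3, eps=0.5)",
         expected = 0.1007, tol = 2e-3,
         fun = function() hopf_threshold(base(0.3, 0.11, 0.5), "mu2",
                                         c(0.085, 0.13))$threshold),
    list(id = "t11", desc = "critical Turing wavenumber kT^2 (mu1=0, mu2=0.41, D=5)",
         expected = 0.1095, tol = 1e-3,
         fun = function() {
           p <- base(0, 0.41, 1)
           eqs <- find_coexistence(p)
           st <- vapply(eqs, function(e) e$stability, character(1))
           e <- eqs[[which(st == "stable")[1]]]
           critical_wavenumber(p, 5, e)$kT2
         }),
    list(id = "t12", desc = "upper end of the instability window of E2 in mu1",
         expected = 0.497, tol = 2e-3,
         fun = function() e2_instability_bound(base(0.1, 0.1, 1)))
  )
  rows <- lapply(items, function(it) {
    val <- tryCatch(it$fun(), error = function(e) {
      warning("reference item ", it$id, " failed: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    data.frame(id = it$id, description = it$desc, computed = val,
               expected = it$expected, tol = it$tol,
               pass = is.finite(val) && abs(val - it$expected) <= it$tol)
  })
  report <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "reference_suite.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    writeLines(c("omzdyn reference suite",
                 utils::capture.output(print(report, row.names = FALSE))),
               file.path(outdir, "reference_suite.txt"))
  }
  report
}

#' Upper end of the instability window of the oxygen-rich
#' zooplankton-free state
#'
#' The zooplankton-free states do not depend on the mortality rates, but
#' their stability does: the third eigenvalue of the full Jacobian at the
#' upper state crosses zero as `mu1` increases. This locates the crossing
#' by bisecting the leading eigenvalue real part.
#'
#' @param params a [model_params()] object (`epsilon` as given; the zero
#'   crossing itself is independent of `epsilon > 0`).
#' @param bracket search bracket in `mu1`.
#' @return The `mu1` value at which the upper zooplankton-free state
#'   stabilizes.
#' @export
e2_instability_bound <- function(params, bracket = c(0.3, 0.7)) {
  zf <- find_zooplankton_free(params)
  if (length(zf) < 2L) stop("upper zooplankton-free state not found",
                            call. = FALSE)
  coords <- zf[[length(zf)]]$coords
  lead <- function(m1) {
    p <- set_param(params, "mu1", m1)
    max(Re(eigen(plankton_jacobian(coords, p), only.values = TRUE)$values))
  }
  stats::uniroot(lead, bracket, tol = 1e-10)$root
}

#' Save / load a run configuration
#'
#' A run configuration bundles the model parameters with spatial-run and
#' analysis settings into one flat JSON document, so that every run can
#' write its exact configuration next to its outputs and be reproduced
#' from it.
#'
#' @param params a [model_params()] object.
#' @param spatial optional named list (e.g. `D, L, dx, dt, T_end,
#'   ic_variant, save_every`).
#' @param analysis optional named list (e.g. `vary, bracket`).
#' @param path JSON file path.
#' @return `read_run_config` returns a list with validated `params` plus
#'   the `spatial` and `analysis` lists; `write_run_config` invisibly
#'   returns `path`.
#' @export
write_run_config <- function(params, path, spatial = NULL, analysis = NULL) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(list(params = unclass(params), spatial = spatial,
                            analysis = analysis),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(params = do.call(model_params, lapply(as.list(x$params), as.numeric)),
       spatial = x$spatial, analysis = x$analysis)
}
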