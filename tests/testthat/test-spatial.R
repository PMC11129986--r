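turing_ref_setup <- function(eps = 1) {
  p <- model_params(mu1 = 0, mu2 = 0.41, epsilon = eps)
  eqs <- find_coexistence(model_params(mu1 = 0, mu2 = 0.41, epsilon = 1))
  list(params = p, eq = eqs[[length(eqs)]])
}

test_that("grid and initial-condition builders follow the stated geometry", {
  g <- grid1d(500, 1)
  expect_identical(g$n, 501L)
  expect_error(grid1d(500, 3), "multiple")
  expect_error(grid1d(10, 1), "16 nodes")
  s <- turing_ref_setup()
  ic <- make_initial(g, s$eq, "standard")
  w <- abs(g$x - 250) < 10
  expect_identical(sum(w), 19L)            # strict inequality window
  expect_equal(ic$c[w], rep(s$eq$coords[1] + 0.1, 19))
  expect_equal(ic$u[w], rep(s$eq$coords[2] + 0.2, 19))
  expect_identical(ic$c[!w], rep(s$eq$coords[1], sum(!w)))
  expect_identical(ic$v, rep(s$eq$coords[3], g$n))
  ic2 <- make_initial(g, s$eq, "depleted")
  expect_equal(ic2$c[w], rep(s$eq$coords[1] - 0.5, 19))
  # depleted variant requires enough background oxygen
  expect_error(make_initial(g, c(0.3, 1, 1), "depleted"), "c\\*")
})

test_that("explicit scheme honors its stability constraint and fixed points", {
  s <- turing_ref_setup()
  g <- grid1d(100, 1)
  expect_error(rd_step(make_initial(g, s$eq), s$params, D = 5, dt = 0.2),
               "stability constraint")
  # a uniform field at the steady state is a fixed point of the scheme
  ic <- make_initial(g, s$eq, half_width = 0)   # no perturbation anywhere
  sim <- simulate_rd(s$params, D = 5, grid = g, dt = 0.01, T_end = 100,
                     init = ic, save_every = 50)
  expect_lt(max(abs(sweep(sim$c, 2, rep(s$eq$coords[1], g$n)))), 1e-10)
  expect_lt(max(abs(sim$v - s$eq$coords[3])), 1e-10)
  # zero-flux: boundary nodes evolve exactly like interior ones
  expect_equal(sim$c[, 1], sim$c[, 50], tolerance = 1e-12)
})

test_that("pure diffusion conserves trapezoid-weighted mass to 1e-12 per step", {
  g <- grid1d(100, 1)
  p <- baseline()
  f <- make_initial(g, c(1.2, 0.9, 0.85))
  m0 <- c(trapz_mass(f$c, g$dx), trapz_mass(f$u, g$dx), trapz_mass(f$v, g$dx))
  for (i in 1:50) f <- rd_step(f, p, D = 5, dt = 0.01, reaction = FALSE)
  m1 <- c(trapz_mass(f$c, g$dx), trapz_mass(f$u, g$dx), trapz_mass(f$v, g$dx))
  expect_lt(max(abs(m1 - m0)), 50 * 1e-12)
})

test_that("compiled core reproduces the reference R step exactly", {
  s <- turing_ref_setup()
  g <- grid1d(60, 1)
  f <- make_initial(g, s$eq)
  for (i in 1:20) f <- rd_step(f, s$params, D = 5, dt = 0.01)
  sim <- simulate_rd(s$params, D = 5, grid = g, dt = 0.01, T_end = 0.2,
                     equilibrium = s$eq, save_every = 0.2)
  expect_equal(unname(sim$c[nrow(sim$c), ]), f$c, tolerance = 1e-13)
  expect_equal(unname(sim$u[nrow(sim$u), ]), f$u, tolerance = 1e-13)
  expect_equal(unname(sim$v[nrow(sim$v), ]), f$v, tolerance = 1e-13)
})

test_that("halving the time step leaves a short run essentially unchanged", {
  s <- turing_ref_setup()
  g <- grid1d(200, 1)
  s1 <- simulate_rd(s$params, D = 5, grid = g, dt = 0.01, T_end = 100,
                    equilibrium = s$eq, save_every = 100)
  s2 <- simulate_rd(s$params, D = 5, grid = g, dt = 0.005, T_end = 100,
                    equilibrium = s$eq, save_every = 100)
  expect_lt(max(abs(s1$c[nrow(s1$c), ] - s2$c[nrow(s2$c), ])), 1e-3)
})

test_that("spatial averages equal the means of the stored snapshots", {
  s <- turing_ref_setup()
  sim <- simulate_rd(s$params, D = 5, grid = grid1d(100, 1), T_end = 50,
                     equilibrium = s$eq, save_every = 10)
  expect_equal(sim$avg$c, rowMeans(sim$c))
  expect_equal(sim$avg$v, rowMeans(sim$v))
  expect_identical(sim$avg$time, sim$times)
  f <- withr::local_tempfile(fileext = ".csv")
  write_averages_csv(sim, f)
  expect_identical(nrow(utils::read.csv(f)), length(sim$times))
})

test_that("OMZ detection reports contiguous low-oxygen intervals", {
  cstar <- 1.2
  flat <- rep(cstar, 101)
  expect_identical(nrow(detect_omz(flat, cstar)$intervals), 0L)
  dip <- flat; dip[30:59] <- 0.1 * cstar
  rep1 <- detect_omz(dip, cstar)
  expect_identical(nrow(rep1$intervals), 1L)
  expect_equal(rep1$intervals$width, 29)
  anoxic <- rep(0, 101)
  repa <- detect_omz(anoxic, cstar)
  expect_identical(nrow(repa$intervals), 1L)
  expect_equal(repa$intervals$width, 100)
  # a single low node is noise, not an OMZ
  one <- flat; one[50] <- 0
  expect_identical(nrow(detect_omz(one, cstar)$intervals), 0L)
})

test_that("regime classifier separates the reference spatial behaviors", {
  s <- turing_ref_setup()
  g <- grid1d(200, 1)
  # short runs are refused
  sim <- simulate_rd(s$params, D = 5, grid = g, T_end = 300, equilibrium = s$eq)
  expect_error(classify_regime(sim), "too short")
  # no-OMZ case: localized fluctuations near the perturbation only
  p24 <- model_params(mu1 = 0.24, mu2 = 0.1575, epsilon = 1)
  e24 <- find_coexistence(p24)[[1]]
  sim24 <- simulate_rd(p24, D = 1, grid = g, T_end = 1200, equilibrium = e24)
  expect_identical(nrow(detect_omz(sim24, e24$coords[1])$intervals), 0L)
  outw <- abs(g$x - 100) >= 30
  dev <- max(abs(sim24$c[nrow(sim24$c), outw] - e24$coords[1]))
  expect_lt(dev, 0.1 * e24$coords[1])
})

test_that("initial oxygen deficit widens the early OMZ but not the outcome", {
  p <- model_params(mu1 = 0, mu2 = 0.41, epsilon = 1)
  e <- find_coexistence(p)[[2]]
  g <- grid1d(200, 1)
  runs <- lapply(c("standard", "depleted"), function(v)
    simulate_rd(p, D = 0.5, grid = g, T_end = 1500, equilibrium = e,
                ic_variant = v))
  labels <- vapply(runs, classify_regime, character(1))
  expect_identical(labels[1], labels[2])
  widths <- vapply(runs, function(r) {
    i <- which(r$times == 100)
    sum(detect_omz(r$c[i, ], e$coords[1], x = r$x)$intervals$width)
  }, numeric(1))
  expect_gte(widths[2], widths[1])
})

test_that("decreasing the timescale parameter degrades spatial sustainability", {
  p24 <- function(eps) model_params(mu1 = 0.24, mu2 = 0.1575, epsilon = eps)
  e <- find_coexistence(p24(1))[[1]]
  g <- grid1d(200, 1)
  labels <- vapply(c(1, 0.5, 0.25, 0.2), function(eps)
    classify_regime(simulate_rd(p24(eps), D = 1, grid = g, T_end = 2000,
                                equilibrium = e)),
    character(1))
  expect_false(any(labels == "homogeneous_steady"))
  # the equal-timescale run keeps the domain oxygenated (no OMZ regime) ...
  expect_false(labels[1] == "global_anoxia")
  # ... anoxia appears as epsilon decreases and persists once reached
  expect_identical(labels[4], "global_anoxia")
  first_anoxic <- which(labels == "global_anoxia")[1]
  expect_true(all(labels[first_anoxic:4] == "global_anoxia"))
})
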