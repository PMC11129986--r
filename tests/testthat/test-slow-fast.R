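test_that("fast-subsystem slices have the documented equilibrium structure", {
  p <- baseline(0.3, 0.1018, 0.5)
  sl <- fast_equilibria(0.6, p)
  expect_identical(nrow(sl$equilibria), 2L)
  # lower-u saddle, upper-u stable
  expect_identical(sl$equilibria$stability, c("saddle", "stable"))
  # beyond the fold the interior equilibria are gone
  expect_identical(nrow(fast_equilibria(1.0, p)$equilibria), 0L)
})

test_that("fast equilibria agree with a brute-force sign-grid scan", {
  p <- baseline(0.3, 0.1018, 0.5)
  set.seed(23)
  for (v0 in c(0.1, 0.3, 0.5, 0.7, 0.85)) {
    sl <- fast_equilibria(v0, p)$equilibria
    hits <- grid_scan_fast(v0, p)
    expect_identical(nrow(sl), if (is.null(hits)) 0L else nrow(hits))
    if (nrow(sl)) {
      for (i in seq_len(nrow(sl))) {
        d <- apply(hits, 1, function(h) max(abs(h - c(sl$c[i], sl$u[i]))))
        expect_lt(min(d), 0.06)   # within the cluster radius of the scan
      }
    }
  }
})

test_that("fold point solves F = G = det(J_sub) = 0 at the printed location", {
  p <- baseline(0.3, 0.1018, 0.5)
  fp <- fold_point(p)
  expect_equal(fp$c_s, 1.26531, tolerance = 1e-4)
  expect_equal(fp$u_s, 1.05229, tolerance = 1e-4)
  expect_equal(fp$v_s, 0.89784, tolerance = 1e-4)
  st <- c(fp$c_s, fp$u_s, fp$v_s)
  expect_lt(max(abs(plankton_rhs(st, p)[1:2])), 1e-9)
  Jsub <- plankton_jacobian(st, p, scaled = FALSE)[1:2, 1:2]
  expect_lt(abs(det(Jsub)), 1e-9)
  # the fold coincides with the saddle-node of the fast slices: slice counts
  # flip from 2 to 0 across v_s
  expect_identical(nrow(fast_equilibria(fp$v_s - 1e-3, p)$equilibria), 2L)
  expect_identical(nrow(fast_equilibria(fp$v_s + 1e-3, p)$equilibria), 0L)
})

test_that("fold discriminants match finite differences and are tol-robust", {
  p <- baseline(0.3, 0.1018, 0.5)
  fp <- fold_point(p)
  st <- c(fp$c_s, fp$u_s, fp$v_s)
  Jfd <- fd_jacobian(st, model_params(mu1 = p$mu1, mu2 = p$mu2, epsilon = 1))
  d1_fd <- Jfd[1, 3] * Jfd[2, 2] - Jfd[1, 2] * Jfd[2, 3]
  d2_fd <- Jfd[1, 3] * Jfd[2, 1] - Jfd[1, 1] * Jfd[2, 3]
  expect_equal(fp$d1, d1_fd, tolerance = 1e-6)
  expect_equal(fp$d2, d2_fd, tolerance = 1e-6)
  for (tol in c(1e-8, 1e-6, 1e-4))
    expect_identical(classify_fold(fp, p, tol = tol)$classification,
                     fp$classification)
  # nu = 0 kills F_v, leaving d1 = -F_u G_v
  p0 <- model_params(nu = 1e-12, mu1 = 0.3, mu2 = 0.1, epsilon = 0.5)
  fp0 <- classify_fold(fp, p0)
  J0 <- plankton_jacobian(st, p0, scaled = FALSE)
  expect_equal(fp0$d1, -J0[1, 2] * J0[2, 3], tolerance = 1e-8)
})

test_that("critical manifold branches split at the fold and meet there", {
  p <- baseline(0.3, 0.1018, 0.5)
  cm <- build_manifold(p)
  s <- cm$samples
  expect_true(all(s$u[s$branch == "attracting"] > cm$fold$u_s))
  expect_true(all(s$u[s$branch == "repelling"] < cm$fold$u_s))
  # branch endpoints converge to the fold within grid resolution
  near <- s[s$v0 > 0.999 * cm$fold$v_s, ]
  expect_gt(nrow(near), 2)
  expect_lt(max(abs(near$u - cm$fold$u_s)), 0.05)
  expect_lt(max(abs(near$c - cm$fold$c_s)), 0.05)
  # trivial (extinction) branch is attracting for all v >= 0
  expect_true(all(cm$trivial$lambda1 < 0))
  expect_true(all(cm$trivial$lambda2 < 0))
  # spot-check branch labels against fast-subsystem eigenvalues
  idx <- seq(1, nrow(s), by = 10)
  for (i in idx) {
    J <- plankton_jacobian(c(s$c[i], s$u[i], s$v0[i]), p,
                           scaled = FALSE)[1:2, 1:2]
    stable <- all(Re(eigen(J, only.values = TRUE)$values) < 0)
    expect_identical(stable, s$branch[i] == "attracting")
  }
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifold_csv(cm, f)
  expect_true(all(c("v0", "c", "u", "branch") %in%
                    names(utils::read.csv(f))))
})

test_that("slow flow follows the implicit differentiation of the manifold", {
  p <- baseline(0.3, 0.09917, 0.5)
  cm <- build_manifold(p)
  att <- cm$samples[cm$samples$branch == "attracting", ]
  att <- att[order(att$v0), ]
  # sign of dv/dtau is the sign of H everywhere on the manifold
  for (i in seq(1, nrow(att), length.out = 12)) {
    pt <- c(att$c[round(i)], att$u[round(i)], att$v0[round(i)])
    sf <- slow_flow(pt, p)
    expect_identical(sign(sf[["dv"]]), sign(plankton_H(pt, p)))
  }
  # oracle: (dc, du) equal the manifold's geometric derivative times dv/dtau
  mid <- att[att$v0 > 0.3 & att$v0 < 0.8 * cm$fold$v_s, ]
  for (i in c(10, 40, 80)) {
    pt <- c(mid$c[i], mid$u[i], mid$v0[i])
    sf <- slow_flow(pt, p)
    dcdv <- (mid$c[i + 1] - mid$c[i - 1]) / (mid$v0[i + 1] - mid$v0[i - 1])
    dudv <- (mid$u[i + 1] - mid$u[i - 1]) / (mid$v0[i + 1] - mid$v0[i - 1])
    expect_equal(sf[["dc"]], dcdv * sf[["dv"]], tolerance = 0.01)
    expect_equal(sf[["du"]], dudv * sf[["dv"]], tolerance = 0.01)
  }
  # the flow accelerates without bound approaching the fold
  tailp <- att[att$v0 < cm$fold$v_s & att$v0 > 0.995 * cm$fold$v_s, ]
  tailp <- tailp[order(tailp$v0), ]
  rates <- vapply(seq_len(nrow(tailp)), function(i)
    abs(slow_flow(c(tailp$c[i], tailp$u[i], tailp$v0[i]), p)[["dc"]]),
    numeric(1))
  expect_gte(length(rates), 5)
  expect_true(all(diff(tail(rates, 5)) > 0))
  # singularity error at the fold itself
  expect_error(slow_flow(c(cm$fold$c_s, cm$fold$u_s, cm$fold$v_s), p),
               "singular")
  # off-manifold points are rejected
  expect_error(slow_flow(c(1, 1, 1), p), "not on the critical manifold")
})

test_that("slow flow points toward the fold on both branches when H > 0", {
  p <- baseline(0.3, 0.1018, 0.5)
  cm <- build_manifold(p)
  fp <- cm$fold
  expect_gt(fp$H_value, 0)
  # H > 0 only survives very close to the fold (its value there is small),
  # so probe slices approaching v_s until both branches sit in H > 0
  found <- FALSE
  for (dv in c(1e-3, 3e-4, 1e-4, 3e-5)) {
    v0 <- fp$v_s - dv
    sl <- fast_equilibria(v0, p, c_max = 3, n_scan = 8000)$equilibria
    if (nrow(sl) != 2L) next
    rep_pt <- c(sl$c[1], sl$u[1], v0)   # u < u_s
    att_pt <- c(sl$c[2], sl$u[2], v0)   # u > u_s
    if (plankton_H(rep_pt, p) > 0 && plankton_H(att_pt, p) > 0) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
  fa <- slow_flow(att_pt, p)
  fr <- slow_flow(rep_pt, p)
  # v increases toward v_s on both branches; u moves toward u_s from both sides
  expect_gt(fa[["dv"]], 0); expect_gt(fr[["dv"]], 0)
  expect_lt(fa[["du"]], 0)   # attracting branch: u > u_s, decreasing
  expect_gt(fr[["du"]], 0)   # repelling branch: u < u_s, increasing
})

test_that("trajectories shadow the attracting branch in the singular limit", {
  p <- baseline(0.3, 0.09917, 0.001)
  cm <- build_manifold(p)
  att <- cm$samples[cm$samples$branch == "attracting", ]
  i0 <- which.min(abs(att$v0 - 0.75))
  y0 <- c(att$c[i0], att$u[i0], att$v0[i0])
  out <- integrate_model(p, y0, seq(0, 1500, by = 5))
  pre_fold <- out[out[, "u"] > cm$fold$u_s + 0.02, , drop = FALSE]
  expect_gt(nrow(pre_fold), 10)
  dists <- vapply(seq_len(nrow(pre_fold)), function(k) {
    min(sqrt((att$c - pre_fold[k, "c"])^2 + (att$u - pre_fold[k, "u"])^2 +
               (att$v0 - pre_fold[k, "v"])^2))
  }, numeric(1))
  expect_lt(max(dists), 0.05)
})
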