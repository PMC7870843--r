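# Nullclines, fixed points, stability, separatrices.

test_that("nullcline reduces to the closed-form leak line when self-activation is disabled", {
  # K -> large disables feedback: dm1/dt = alpha*beta - delta*m1, so the
  # module-1 nullcline is the constant line m1 = alpha*beta/delta
  p <- circuit_params(K1 = 1e9, beta1 = 0.2, alpha1 = 50, delta1 = 2)
  pr <- induction_protocol(d_lara = 9.5e-4)
  nc <- nullcline(1, p, pr, "SBS_COMPETITION", grid = 61)
  expect_gt(nrow(nc), 50)
  expect_equal(nc$m1, rep(50 * 0.2 / 2, nrow(nc)), tolerance = 1e-6)
})

test_that("the ideal-circuit module-1 nullcline is S-shaped (3 roots over an interval)", {
  cfg <- all_presets()$ideal_1b
  nc <- nullcline(1, cfg$p, cfg$pr, cfg$v, grid = 200)
  roots_per_slice <- table(nc$m2)
  expect_equal(max(roots_per_slice), 3)
  expect_equal(min(roots_per_slice), 1)
})

test_that("resource competition closes the module-1 nullcline at high module-2 load", {
  # with competition the high-m1 branch is lost above a fold threshold
  cfg <- all_presets()$cbs_comp
  nc <- nullcline(1, cfg$p, cfg$pr, cfg$v, grid = 150)
  b2 <- state_bound(cfg$p)[2]
  hi_m2 <- nc[nc$m2 > 0.7 * b2, ]
  lo_m2 <- nc[nc$m2 < 0.05 * b2, ]
  expect_true(any(lo_m2$m1 > 30))   # activated branch exists at low load
  expect_true(all(hi_m2$m1 < 30))   # and is gone under heavy module-2 load
})

test_that("fold detection marks branch-count changes of exactly two", {
  for (nm in c("ideal_1b", "cbs_comp")) {
    cfg <- all_presets()[[nm]]
    folds <- nullcline_folds(1, cfg$p, cfg$pr, cfg$v, grid = 150)
    expect_gt(nrow(folds), 0)
    expect_true(all(abs(folds$branch_count_high - folds$branch_count_low) == 2))
  }
})

test_that("uninduced leak-free system has a single stable fixed point at the origin", {
  p <- circuit_params(beta1 = 0, beta2 = 0)
  fps <- find_fixed_points(p, induction_protocol(), "CBS_IDEAL")
  expect_equal(nrow(fps), 1)
  expect_equal(c(fps$m1, fps$m2), c(0, 0), tolerance = 1e-6)
  expect_equal(fps$stability, "STABLE")
})

test_that("ideal circuit at reference induction has 3 stable states and 2 saddles", {
  cfg <- all_presets()$ideal_1b
  fps <- find_fixed_points(cfg$p, cfg$pr, cfg$v)
  expect_equal(sum(fps$stability == "STABLE"), 3)
  expect_equal(sum(fps$stability == "SADDLE"), 2)
})

test_that("every reported fixed point is a root to tolerance", {
  for (cfg in all_presets()[c("ideal_1b", "cbs_comp", "sbs")]) {
    fps <- find_fixed_points(cfg$p, cfg$pr, cfg$v)
    for (i in seq_len(nrow(fps))) {
      d <- circuit_rhs(c(fps$m1[i], fps$m2[i]), cfg$pr$t_end, cfg$p, cfg$pr,
                       cfg$v)
      expect_lt(max(abs(c(d$dm1, d$dm2))),
                1e-8 * max(state_bound(cfg$p)) * 1.1)
    }
  }
})

test_that("stability classification: exact Jacobian at the leak-free origin", {
  p <- circuit_params(beta1 = 0, beta2 = 0, delta1 = 1.3, delta2 = 0.7)
  cl <- classify_stability(c(0, 0), p, induction_protocol(), "CBS_IDEAL")
  expect_equal(sort(Re(cl$eigenvalues)), c(-1.3, -0.7), tolerance = 1e-4)
  expect_equal(cl$stability, "STABLE")
})

test_that("saddles have eigenvalues of opposite sign and stability matches perturbation dynamics", {
  cfg <- all_presets()$sbs
  fps <- find_fixed_points(cfg$p, cfg$pr, cfg$v)
  bound <- state_bound(cfg$p)
  eps <- 0.02 * bound
  long <- induction_protocol(d_lara = cfg$pr$d_lara, d_c6 = cfg$pr$d_c6,
                             t_end = 120)
  for (i in seq_len(nrow(fps))) {
    re <- c(fps$eig1_re[i], fps$eig2_re[i])
    if (fps$stability[i] == "SADDLE") expect_lt(prod(re), 0)
    loc <- c(fps$m1[i], fps$m2[i])
    returns <- logical(0)
    for (dx in c(-1, 0, 1)) for (dy in c(-1, 0, 1)) {
      if (dx == 0 && dy == 0) next
      init <- pmax(loc + c(dx, dy) * eps, 0)
      tr <- integrate_circuit(cfg$p, long, cfg$v, init = init,
                              times = c(0, 120))
      end <- c(tr$m1[2], tr$m2[2])
      returns <- c(returns, sqrt(sum((end - loc)^2)) < 0.03 * max(bound))
    }
    if (fps$stability[i] == "STABLE") expect_true(all(returns))
    else expect_false(all(returns))
  }
})

test_that("separatrices partition neighborhoods into distinct basins", {
  cfg <- all_presets()$sbs
  fps <- find_fixed_points(cfg$p, cfg$pr, cfg$v)
  sad <- fps[fps$stability == "SADDLE", ]
  expect_equal(nrow(sad), 2)
  thr <- fate_thresholds(fps, cfg$p)
  long <- induction_protocol(d_lara = cfg$pr$d_lara, d_c6 = cfg$pr$d_c6,
                             t_end = 200)
  n_diff <- 0; n_tot <- 0
  for (i in seq_len(nrow(sad))) {
    sep <- separatrix(sad[i, ], cfg$p, cfg$pr, cfg$v)
    expect_error(separatrix(fps[fps$stability == "STABLE", ][1, ],
                            cfg$p, cfg$pr, cfg$v), "SADDLE|saddle")
    # points straddling the curve flow to different attractors
    idx <- round(seq(5, nrow(sep) - 5, length.out = 7))
    for (k in idx) {
      tang <- sep[k + 1, ] - sep[k - 1, ]
      nrm <- c(-tang$m2, tang$m1)
      nrm <- nrm / sqrt(sum(nrm^2)) * 0.04 * max(state_bound(cfg$p))
      f <- character(2)
      for (s in 1:2) {
        init <- pmax(unlist(sep[k, ]) + (if (s == 1) nrm else -nrm), 0)
        tr <- integrate_circuit(cfg$p, long, cfg$v, init = init,
                                times = c(0, 200))
        f[s] <- classify_fate(c(tr$m1[2], tr$m2[2]), thr)
      }
      n_tot <- n_tot + 1
      if (f[1] != f[2]) n_diff <- n_diff + 1
    }
  }
  expect_gte(n_diff / n_tot, 0.85)
})

test_that("phase portrait is mirror-symmetric under swapping the two modules", {
  p <- circuit_params(alpha1 = 120, alpha2 = 80, beta1 = 0.03, beta2 = 0.05,
                      K1 = 25, K2 = 18, n1 = 2, n2 = 3, delta1 = 1,
                      delta2 = 1.5, lambda1 = 0.8, lambda2 = 1.1,
                      Ka = 4e-4, Kc = 2.1e-8)
  swapped <- circuit_params(alpha1 = 80, alpha2 = 120, beta1 = 0.05,
                            beta2 = 0.03, K1 = 18, K2 = 25, n1 = 3, n2 = 2,
                            delta1 = 1.5, delta2 = 1, lambda1 = 1.1,
                            lambda2 = 0.8, Ka = 2.1e-8, Kc = 4e-4)
  pr <- induction_protocol(d_lara = 9.5e-4, d_c6 = 5e-8)
  prs <- induction_protocol(d_lara = 5e-8, d_c6 = 9.5e-4)
  f1 <- find_fixed_points(p, pr, "SBS_COMPETITION")
  f2 <- find_fixed_points(swapped, prs, "SBS_COMPETITION")
  expect_equal(nrow(f1), nrow(f2))
  a <- f1[order(f1$m1, f1$m2), c("m1", "m2")]
  b <- f2[order(f2$m2, f2$m1), c("m2", "m1")]
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)), tolerance = 1e-4)
})

test_that("portrait bundles are deterministic and exportable", {
  cfg <- all_presets()$ideal_1c
  pp1 <- phase_portrait(cfg$p, cfg$pr, cfg$v, grid = 80, grid_density = 60)
  pp2 <- phase_portrait(cfg$p, cfg$pr, cfg$v, grid = 80, grid_density = 60)
  expect_identical(pp1$fixed_points, pp2$fixed_points)
  expect_identical(pp1$nullcline1, pp2$nullcline1)
  td <- withr::local_tempdir()
  paths <- write_portrait_csv(pp1, td)
  expect_true(all(file.exists(paths)))
  fp_back <- utils::read.csv(paths[2])
  expect_equal(nrow(fp_back), nrow(pp1$fixed_points))
})
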