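# Exact SSA engine: birth-death reductions with analytic stationary laws,
# seed determinism, dose-step epochs, and winner-takes-all kinetics.

# Zero doses pin each promoter at its leak (input = 0), so with lambda = 0
# each species is an independent linear birth-death process with birth rate
# volume * alpha * beta and unit death rate per molecule.
bd_params <- function(k = 8, delta = 1)
  circuit_params(alpha1 = k, alpha2 = k, beta1 = 0.999, beta2 = 0.999,
                 delta1 = delta, delta2 = delta, lambda1 = 0, lambda2 = 0)
# (beta < 1 bound: use alpha * beta = k via alpha = k/0.999)

test_that("birth-death reduction: time-average matches k/delta and the stationary law is Poisson", {
  k <- 8
  p <- bd_params(k / 0.999)
  pr <- induction_protocol(t_end = 4000)
  tr <- ssa_trajectory(p, pr, "SBS_COMPETITION", volume = 1, seed = 101,
                       init = c(k, k), sample_times = pr$t_end,
                       occupancy_max = c(60, 60))
  expect_gt(tr$n_events, 1e5)
  occ1 <- rowSums(tr$occupancy)
  w <- occ1 / sum(occ1)
  mean_occ <- sum((0:60) * w)
  # 3 standard errors of the time-average (effective samples ~ events/2)
  se <- sqrt(k / (tr$n_events / 4))
  expect_lt(abs(mean_occ - k), 3 * se + 0.05)

  # independent endpoint samples across cells: chi-square against Poisson(k)
  ends <- vapply(1:300, function(i) {
    ssa_trajectory(p, induction_protocol(t_end = 30), "SBS_COMPETITION",
                   volume = 1, seed = 2000 + i, init = c(k, k),
                   sample_times = 30)$final[1]
  }, 0)
  bins <- c(-Inf, 4:12, Inf)
  obs <- table(cut(ends, bins))
  pp <- diff(ppois(c(-1, 4:12, Inf), k))
  chi <- sum((as.numeric(obs) - 300 * pp)^2 / (300 * pp))
  expect_lt(chi, qchisq(0.99, df = length(pp) - 1))
})

test_that("identical seeds give identical trajectories; different seeds differ", {
  cfg <- all_presets()$sbs
  t1 <- ssa_trajectory(cfg$p, cfg$pr, cfg$v, volume = 5, seed = 7)
  t2 <- ssa_trajectory(cfg$p, cfg$pr, cfg$v, volume = 5, seed = 7)
  t3 <- ssa_trajectory(cfg$p, cfg$pr, cfg$v, volume = 5, seed = 8)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$n_events, t2$n_events)
  expect_false(identical(t1$states, t3$states))
})

test_that("dose epochs: C6 propensities switch on exactly at t_c6", {
  p <- preset("SBS_COMPETITION")
  # C6 only, added at t = 10: module 2 must stay at leak level before,
  # and activate after
  pr <- induction_protocol(d_c6 = 5e-6, t_c6 = 10, t_end = 30)
  tr <- ssa_trajectory(p, pr, "SBS_COMPETITION", volume = 5, seed = 12,
                       sample_times = c(9.9, 30))
  expect_lt(tr$states[1, "N2"], 0.3 * 5 * 100)   # leak-ish before addition
  expect_gt(tr$states[2, "N2"], 0.5 * 5 * 40)    # activated after

  # t_c6 = 0 is bit-identical to a protocol with C6 present from the start
  pr0 <- induction_protocol(d_c6 = 5e-6, t_c6 = 0, t_end = 10)
  tr0 <- ssa_trajectory(p, pr0, "SBS_COMPETITION", volume = 5, seed = 3)
  trA <- ssa_trajectory(p, induction_protocol(d_c6 = 5e-6, t_end = 10),
                        "SBS_COMPETITION", volume = 5, seed = 3)
  expect_identical(tr0$states, trA$states)
  # and an addition at t_end is bit-identical to no C6 at all
  prL <- induction_protocol(d_c6 = 5e-6, t_c6 = 10, t_end = 10)
  trL <- ssa_trajectory(p, prL, "SBS_COMPETITION", volume = 5, seed = 3)
  trN <- ssa_trajectory(p, induction_protocol(t_end = 10),
                        "SBS_COMPETITION", volume = 5, seed = 3)
  expect_identical(trL$states, trN$states)
})

test_that("fate classification: quadrants, tie-break, and portrait consistency", {
  thr <- c(10, 20)
  expect_equal(classify_fate(c(0, 0), thr), "LL")
  expect_equal(classify_fate(c(10, 20), thr), "HH")  # >= convention
  expect_equal(classify_fate(c(15, 3), thr), "LH")   # module 1 high -> GFP high
  expect_equal(classify_fate(c(3, 25), thr), "HL")
  cfg <- all_presets()$sbs
  fps <- find_fixed_points(cfg$p, cfg$pr, cfg$v)
  thr2 <- fate_thresholds(fps, cfg$p)
  st <- fps[fps$stability == "STABLE", ]
  expect_equal(classify_fate(as.matrix(st[, c("m1", "m2")]), thr2), st$fate)
})

test_that("identical initial conditions split into multiple fates at the reference doses", {
  cfg <- all_presets()$sbs
  fd <- fate_distribution(cfg$p, cfg$pr, cfg$v, volume = 5, n_cells = 120,
                          seed = 21)
  expect_equal(sum(fd$fractions), 1)
  expect_gte(length(fd$fractions), 2)
  # per-cell seeds are counter-derived: cell i is reproducible in isolation
  tr_i <- ssa_trajectory(cfg$p, cfg$pr, cfg$v, volume = 5,
                         seed = cbswitch:::cell_seed(21, 5),
                         sample_times = cfg$pr$t_end)
  expect_equal(unname(fd$terminal[5, ]), unname(tr_i$final))
})

test_that("raising the C6 dose monotonically promotes the module-2 winner state", {
  cfg <- all_presets()$sbs
  doses <- 5e-8 * 10^seq(-1, 1, length.out = 5)
  hl <- vapply(seq_along(doses), function(i) {
    pr <- induction_protocol(d_lara = 9.5e-4, d_c6 = doses[i])
    fd <- fate_distribution(cfg$p, pr, cfg$v, volume = 5, n_cells = 60,
                            seed = 40 + i)
    sum(fd$fractions[names(fd$fractions) == "HL"])
  }, 0)
  expect_true(all(diff(hl) >= -0.02))  # nondecreasing up to sampling noise
  expect_lt(hl[1], 0.2)
  expect_gt(hl[5], 0.8)
})

test_that("large volumes recover the deterministic fate", {
  cfg <- all_presets()$sbs
  pr <- induction_protocol(d_lara = 9.5e-6, d_c6 = 5e-6)  # clear HL corner
  fps <- find_fixed_points(cfg$p, pr, cfg$v)
  thr <- fate_thresholds(fps, cfg$p)
  det <- classify_fate(terminal_state(cfg$p, pr, cfg$v)$state, thr)
  fd <- fate_distribution(cfg$p, pr, cfg$v, volume = 60, n_cells = 12,
                          seed = 5, thresholds = thr * 60)
  expect_equal(unname(fd$fractions[det]), 1)
})

test_that("invalid stochastic inputs are rejected", {
  cfg <- all_presets()$sbs
  expect_error(ssa_trajectory(cfg$p, cfg$pr, cfg$v), "seed")
  expect_error(ssa_trajectory(cfg$p, cfg$pr, cfg$v, volume = 0, seed = 1),
               "volume")
  expect_error(fate_distribution(cfg$p, cfg$pr, cfg$v, n_cells = 0, seed = 1),
               "n_cells")
})
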