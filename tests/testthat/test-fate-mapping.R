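# Dose-space and protocol-space fate maps.

test_that("zero-dose degenerate map is LL and deterministic maps are reproducible", {
  cfg <- all_presets()$sbs
  m0 <- dose_sweep(cfg$v, cfg$p, 0, 0, thresholds = c(20, 20))
  expect_equal(m0$grid$label, "LL")
  ax1 <- dose_axis(9.5e-4, 5); ax2 <- dose_axis(5e-8, 5)
  m1 <- dose_sweep(cfg$v, cfg$p, ax1, ax2)
  m2 <- dose_sweep(cfg$v, cfg$p, ax1, ax2)
  expect_identical(m1$grid, m2$grid)
})

test_that("the separated-switch dose plane shows the four-corner arrangement", {
  cfg <- all_presets()$sbs
  map <- dose_sweep(cfg$v, cfg$p, dose_axis(9.5e-4, 10), dose_axis(5e-8, 10))
  g <- map$grid
  expect_equal(count_fate_regions(map), 4)
  corner_label <- function(lo1, lo2) {
    q1 <- if (lo1) g$axis1 <= sort(unique(g$axis1))[2]
          else g$axis1 >= rev(sort(unique(g$axis1)))[2]
    q2 <- if (lo2) g$axis2 <= sort(unique(g$axis2))[2]
          else g$axis2 >= rev(sort(unique(g$axis2)))[2]
    names(which.max(table(g$label[q1 & q2])))
  }
  expect_equal(corner_label(TRUE, TRUE), "LL")
  expect_equal(corner_label(TRUE, FALSE), "HL")   # high C6, low L-ara
  expect_equal(corner_label(FALSE, TRUE), "LH")   # high L-ara, low C6
  expect_equal(corner_label(FALSE, FALSE), "HH")  # balanced high
})

test_that("module 1 activates first along the L-ara axis at zero C6", {
  cfg <- all_presets()$sbs
  map <- dose_sweep(cfg$v, cfg$p, dose_axis(9.5e-4, 12), 0)
  lab <- map$grid$label[order(map$grid$axis1)]
  non_ll <- setdiff(unique(lab), c("LL", "UNSETTLED"))
  expect_equal(non_ll, "LH")
  first_non_ll <- lab[!lab %in% c("LL", "UNSETTLED")][1]
  expect_equal(first_non_ll, "LH")
})

test_that("region counting handles uniform and checkerboard label fields", {
  cfg <- all_presets()$sbs
  uni <- dose_sweep(cfg$v, cfg$p, 0, 0, thresholds = c(20, 20))
  expect_equal(count_fate_regions(uni), 1)
  board <- structure(list(
    grid = within(expand.grid(axis1 = 1:4, axis2 = 1:4),
                  label <- ifelse((axis1 + axis2) %% 2 == 0, "LL", "HH")),
    axis1 = "a", axis2 = "b", mode = "DETERMINISTIC"), class = "fate_map")
  n <- count_fate_regions(board, connected = TRUE)
  expect_equal(as.integer(n), 2)
  expect_equal(attr(n, "components"), 16)  # checkerboard: every cell isolated
  empty <- structure(list(grid = data.frame(axis1 = numeric(0),
                                            axis2 = numeric(0),
                                            label = character(0)),
                          axis1 = "a", axis2 = "b",
                          mode = "DETERMINISTIC"), class = "fate_map")
  expect_error(count_fate_regions(empty), "empty")
})

test_that("coactivation fraction: all-HH map gives 1; competition circuit gives ~0", {
  allhh <- structure(list(
    grid = within(expand.grid(axis1 = 1:3, axis2 = 1:3), label <- "HH"),
    axis1 = "a", axis2 = "b", mode = "DETERMINISTIC"), class = "fate_map")
  expect_equal(coactivation_fraction(allhh), 1)
  cfg <- all_presets()$cbs_comp
  map <- dose_sweep(cfg$v, cfg$p, dose_axis(9.5e-4, 8), dose_axis(5e-8, 4))
  expect_lt(coactivation_fraction(map), 0.02)
})

test_that("coactivation shrinks monotonically with competition strength", {
  cfg <- all_presets()$sbs
  ax1 <- dose_axis(9.5e-4, 8); ax2 <- dose_axis(5e-8, 8)
  co <- vapply(c(0, 0.5, 1, 1.5, 2), function(lam) {
    p <- circuit_params(lambda1 = lam, lambda2 = lam, .base = cfg$p)
    coactivation_fraction(dose_sweep(cfg$v, p, ax1, ax2,
                                     thresholds = c(20, 20)))
  }, 0)
  expect_true(all(diff(co) <= 1e-12))
  expect_gt(co[1], co[5])
})

test_that("sequential induction: protocol equivalence at t_c6 = 0 and late-addition commitment", {
  cfg <- all_presets()$sbs
  c6ax <- dose_axis(5e-8, 5)
  thr <- c(23, 23)
  seq0 <- sequential_induction_map(cfg$v, cfg$p, c6ax, 0, d_lara = 9.5e-4,
                                   thresholds = thr)
  sweep0 <- dose_sweep(cfg$v, cfg$p, 9.5e-4, c6ax, thresholds = thr)
  expect_equal(seq0$grid$label[order(seq0$grid$axis1)],
               sweep0$grid$label[order(sweep0$grid$axis2)])
  # late C6 addition: module 1 is committed, the cell stays GFP-high
  late <- terminal_state(cfg$p, induction_protocol(d_lara = 9.5e-4,
                                                   d_c6 = 5e-8, t_c6 = 6,
                                                   t_end = 24), cfg$v)
  expect_equal(classify_fate(late$state, thr), "LH")
  # control: without L-ara the same late C6 still activates module 2
  ctrl <- terminal_state(cfg$p, induction_protocol(d_lara = 0, d_c6 = 5e-8,
                                                   t_c6 = 6, t_end = 24),
                         cfg$v)
  expect_equal(classify_fate(ctrl$state, thr), "HL")
})

test_that("stochastic sequential induction shifts fates from HL plurality toward LH", {
  cfg <- all_presets()$sbs
  frac_at <- function(tc) {
    pr <- induction_protocol(d_lara = 9.5e-4, d_c6 = 5e-8, t_c6 = tc)
    fate_distribution(cfg$p, pr, cfg$v, volume = 5, n_cells = 80,
                      seed = 17)$fractions
  }
  f0 <- frac_at(0); f4 <- frac_at(4)
  expect_equal(names(which.max(f0)), "HL")
  expect_equal(names(which.max(f4)), "LH")
  expect_gt(sum(f4[names(f4) == "LH"]), sum(f0[names(f0) == "LH"]))
})

test_that("aTc releases the link: module 1 wins without aTc, module 2 with it", {
  p <- preset("CBS_HYBRID_TETR")
  map <- atc_sweep(p, atc_axis = c(0, 100), d_lara = 9.5e-4)
  g <- map$grid
  expect_equal(g$label[g$axis2 == 0], "LH")
  expect_equal(g$label[g$axis2 == 100], "HL")
  zero <- atc_sweep(p, atc_axis = c(0, 100), lara_axis = 1e-7,
                    thresholds = c(60, 25))
  expect_true(all(zero$grid$label == "LL"))
})

test_that("fate maps export as long-format CSV with metadata sidecar", {
  cfg <- all_presets()$sbs
  map <- dose_sweep(cfg$v, cfg$p, dose_axis(9.5e-4, 3), dose_axis(5e-8, 3))
  td <- withr::local_tempdir()
  paths <- write_fate_map_csv(map, file.path(td, "map.csv"))
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(nrow(back), 9)
  meta <- utils::read.csv(paths[2])
  expect_setequal(meta$key, c("axis1", "axis2", "mode"))
})
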