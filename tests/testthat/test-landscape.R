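# CME generator, stationary distribution, quasi-potential.

test_that("the 1-species birth-death generator matches the hand-built matrix", {
  k <- 6; delta <- 1; N <- 25
  p <- circuit_params(alpha1 = k / 0.999, beta1 = 0.999, alpha2 = 1,
                      beta2 = 0.5, delta1 = delta)
  gen <- build_generator(p, induction_protocol(), "SBS_COMPETITION",
                         volume = 1, truncation = c(N, 0),
                         check_attractors = FALSE)
  Q <- as.matrix(gen$Q)
  H <- matrix(0, N + 1, N + 1)
  for (i in 0:(N - 1)) H[i + 2, i + 1] <- k            # birth
  for (i in 1:N) H[i, i + 1] <- delta * i              # death
  diag(H) <- -colSums(H)
  expect_equal(unname(Q), unname(H), tolerance = 1e-12)
  expect_lt(max(abs(Matrix::colSums(gen$Q))), 1e-10)
})

test_that("birth-death stationary law is Poisson within truncation", {
  k <- 6
  p <- circuit_params(alpha1 = k / 0.999, beta1 = 0.999,
                      alpha2 = k / 0.999, beta2 = 0.999)
  gen <- build_generator(p, induction_protocol(), "SBS_COMPETITION",
                         volume = 1, truncation = c(40, 40),
                         check_attractors = FALSE)
  d <- stationary_distribution(gen)
  expect_equal(sum(d$probabilities), 1, tolerance = 1e-10)
  expect_true(all(d$probabilities >= 0))
  marg <- rowSums(d$probabilities)
  pois <- dpois(0:40, k); pois[41] <- pois[41] + 1 - ppois(40, k)
  expect_lt(0.5 * sum(abs(marg - pois)), 1e-6)
  # two unlinked modules: the joint law is the product of its marginals
  joint <- d$probabilities
  prod_form <- outer(rowSums(joint), colSums(joint))
  expect_lt(0.5 * sum(abs(joint - prod_form)), 1e-6)
})

test_that("doubling the truncation leaves the stationary distribution unchanged", {
  cfg <- all_presets()$sbs
  fps <- find_fixed_points(cfg$p, cfg$pr, cfg$v)
  amax <- apply(fps[fps$stability == "STABLE", c("m1", "m2")], 2, max) * 0.3
  g1 <- build_generator(cfg$p, cfg$pr, cfg$v, volume = 0.3,
                        truncation = ceiling(3.5 * amax))
  tr2 <- c(g1$N1max, g1$N2max) * 2
  g2 <- build_generator(cfg$p, cfg$pr, cfg$v, volume = 0.3, truncation = tr2)
  d1 <- stationary_distribution(g1)
  d2 <- stationary_distribution(g2)
  p2_clip <- d2$probabilities[1:(g1$N1max + 1), 1:(g1$N2max + 1)]
  expect_lt(0.5 * sum(abs(d1$probabilities - p2_clip)) +
              0.5 * (1 - sum(p2_clip)), 1e-6)
})

test_that("a too-small lattice raises a TRUNCATION error naming the attractor", {
  cfg <- all_presets()$sbs
  expect_error(build_generator(cfg$p, cfg$pr, cfg$v, volume = 1,
                               truncation = c(10, 10)), "TRUNCATION")
})

test_that("quasi-potential: uniform law is flat, Poisson well sits at the mode", {
  fake <- structure(list(probabilities = matrix(1 / 100, 10, 10),
                         N1max = 9, N2max = 9, volume = 1, residual = 0,
                         truncation_mass_leak = 0, generator = list()),
                    class = "stationary_distribution")
  qp <- quasi_potential(fake)
  expect_equal(max(qp$potential) - min(qp$potential), 0)
  expect_error(quasi_potential(fake, floor = 0), "floor")

  k <- 6
  p <- circuit_params(alpha1 = k / 0.999, beta1 = 0.999,
                      alpha2 = k / 0.999, beta2 = 0.999)
  gen <- build_generator(p, induction_protocol(), "SBS_COMPETITION",
                         volume = 1, truncation = c(40, 40),
                         check_attractors = FALSE)
  qp2 <- quasi_potential(stationary_distribution(gen))
  expect_equal(nrow(qp2$wells), 1)
  expect_equal(c(qp2$wells$N1, qp2$wells$N2), c(k, k), tolerance = 0.35)
})

test_that("potential wells coincide with the deterministic attractors on the presets", {
  for (nm in c("sbs", "cbs_comp")) {
    cfg <- all_presets()[[nm]]
    gen <- build_generator(cfg$p, cfg$pr, cfg$v, volume = 0.8)
    d <- stationary_distribution(gen)
    expect_lt(d$residual, 1e-10)
    qp <- quasi_potential(d)
    match <- qp$well_attractor_match
    expect_equal(nrow(match), 3)  # all presets here are tristable
    expect_true(all(match$distance <
                      0.15 * sqrt(gen$N1max^2 + gen$N2max^2)))
  }
})

test_that("the one-strain competition landscape has no coactivation well", {
  cfg <- all_presets()$cbs_comp
  gen <- build_generator(cfg$p, cfg$pr, cfg$v, volume = 0.8)
  qp <- quasi_potential(stationary_distribution(gen))
  fps <- find_fixed_points(cfg$p, cfg$pr, cfg$v)
  thr <- fate_thresholds(fps, cfg$p) * 0.8  # scale to counts
  well_fates <- classify_fate(cbind(qp$wells$N1, qp$wells$N2), thr)
  expect_false("HH" %in% well_fates)
  expect_setequal(well_fates, c("LL", "LH", "HL"))
})

test_that("SSA endpoint ensemble agrees with the CME stationary law", {
  cfg <- all_presets()$sbs
  vol <- 0.15
  pr <- induction_protocol(d_lara = cfg$pr$d_lara, d_c6 = cfg$pr$d_c6,
                           t_end = 200)
  gen <- build_generator(cfg$p, pr, cfg$v, volume = vol)
  d <- stationary_distribution(gen)
  counts <- matrix(0, gen$N1max + 1, gen$N2max + 1)
  for (i in 1:10000) {
    tr <- ssa_trajectory(cfg$p, pr, cfg$v, volume = vol,
                         seed = cbswitch:::cell_seed(11, i),
                         sample_times = 200)
    a <- min(tr$final[1], gen$N1max); b <- min(tr$final[2], gen$N2max)
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
  }
  tv <- 0.5 * sum(abs(counts / sum(counts) - d$probabilities))
  expect_lt(tv, 0.05)
})

test_that("landscape CSV export round-trips", {
  k <- 4
  p <- circuit_params(alpha1 = k / 0.999, beta1 = 0.999,
                      alpha2 = k / 0.999, beta2 = 0.999)
  gen <- build_generator(p, induction_protocol(), "SBS_COMPETITION",
                         volume = 1, truncation = c(20, 20),
                         check_attractors = FALSE)
  d <- stationary_distribution(gen)
  td <- withr::local_tempdir()
  paths <- write_landscape_csv(d, quasi_potential(d), td)
  expect_true(all(file.exists(paths)))
  back <- as.matrix(utils::read.table(paths[1], sep = ","))
  expect_equal(unname(back), unname(d$probabilities), tolerance = 1e-12)
})
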