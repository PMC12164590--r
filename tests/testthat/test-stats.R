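test_that("lane Welch test matches the textbook formula and t.test", {
  cube <- profile_cube(list(
    P1 = list(WT = cbind(c(10, 12, 11)), mut = cbind(c(20, 22, 21))),
    P2 = list(WT = cbind(c(1, 2, 3)), mut = cbind(c(1, 2, 3)))
  ))
  res <- welch_lane_test(cube, reference = "WT", test = "mut")

  r1 <- res[res$protein_id == "P1", ]
  expect_equal(r1$t, 10 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r1$df, 4, tolerance = 1e-9)
  oracle <- t.test(c(20, 22, 21), c(10, 12, 11))
  expect_equal(r1$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(r1$t, unname(oracle$statistic), tolerance = 1e-12)

  r2 <- res[res$protein_id == "P2", ]
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)

  # |t| and p invariant under swapping the group labels
  swapped <- welch_lane_test(cube, reference = "mut", test = "WT")
  expect_equal(abs(swapped$t), abs(res$t))
  expect_equal(swapped$p, res$p)
})

test_that("zero-variance groups get the documented degenerate policy", {
  cube <- profile_cube(list(
    Peq = list(WT = cbind(c(2, 2, 2)), mut = cbind(c(2, 2, 2))),
    Pdiff = list(WT = cbind(c(2, 2, 2)), mut = cbind(c(5, 5, 5)))
  ))
  res <- welch_lane_test(cube, reference = "WT", test = "mut")
  eq <- res[res$protein_id == "Peq", ]
  expect_equal(eq$p, 1)
  expect_true(eq$degenerate)
  diff <- res[res$protein_id == "Pdiff", ]
  expect_equal(diff$p, 0)
  expect_equal(diff$t, Inf)
  expect_true(diff$degenerate)
})

test_that("band test over the full lane equals the lane test", {
  cfg <- sim_config(seed = 8, noise_cv = 0.2)
  sim <- simulate_dataset(demo_complex_specs(), cfg)
  full <- band_test(sim$cube, band_window("all", 1, 36))
  lane <- welch_lane_test(sim$cube)
  expect_equal(full$p, lane$p, tolerance = 1e-12)
  expect_equal(full$t, lane$t, tolerance = 1e-12)

  # all-zero window in both strains: degenerate policy p = 1
  cube0 <- profile_cube(list(
    P1 = list(WT = rbind(c(1, 0, 0), c(2, 0, 0)),
              mut = rbind(c(3, 0, 0), c(4, 0, 0)))
  ))
  res <- band_test(cube0, band_window("empty", 2, 3), reference = "WT",
                   test = "mut")
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
})

test_that("a planted band difference is detected reliably", {
  # 10-fold test-only accumulation in the RCII window, moderate noise
  specs <- list(
    complex_spec("C", c(X = 1), list(
      assembly_state("RCIIish", 22, 0.7, 2, 20)
    )),
    complex_spec("A", c(anchor = 1), list(assembly_state("s", 10, 1, 100, 100)))
  )
  hits <- vapply(1:50, function(seed) {
    sim <- simulate_dataset(specs, sim_config(seed = seed, noise_cv = 0.1))
    band_test(sim$cube, "RCII", proteins = "X")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("profile distances match hand-computed Euclidean geometry", {
  # identical profiles
  expect_equal(profile_distance(c(1, 2), c(1, 2))$adjusted, 0)
  # disjoint unit peaks
  d <- profile_distance(c(1, 0, 0), c(0, 1, 0))
  expect_equal(d$euclidean, sqrt(2), tolerance = 1e-12)
  expect_equal(d$amplitude, 1)
  # hand l2: wt = (2,0,...), mut = (0,1,0,...)
  d2 <- profile_distance(c(2, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(d2$euclidean, sqrt(5), tolerance = 1e-12)
  expect_equal(d2$adjusted, sqrt(5) / 2, tolerance = 1e-12)
  # both all-zero: flagged, adjusted 0
  d0 <- profile_distance(c(0, 0), c(0, 0))
  expect_true(d0$degenerate)
  expect_equal(d0$adjusted, 0)
  expect_error(profile_distance(c(1, 2), c(1, 2, 3)), "length")
})

test_that("adjusted distance is invariant under joint positive scaling", {
  set.seed(2)
  for (i in 1:20) {
    x <- runif(36); y <- runif(36); c_scale <- 10^runif(1, -6, 6)
    expect_equal(profile_distance(c_scale * x, c_scale * y)$adjusted,
                 profile_distance(x, y)$adjusted, tolerance = 1e-12)
  }
})

test_that("per-strain amplitude option reports both denominators", {
  d <- profile_distance(c(2, 0), c(0, 1), amplitude = "per_strain")
  expect_equal(d$adjusted_ref, sqrt(5) / 2, tolerance = 1e-12)
  expect_equal(d$adjusted_test, sqrt(5), tolerance = 1e-12)
})

test_that("Holm adjustment follows the step-down hand computation", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.02, 0.02, 0.02)), c(0.06, 0.06, 0.06))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # monotone in sorted order and never below the raw p
  set.seed(3)
  for (i in 1:10) {
    p <- runif(7)
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("blot normalization maps the reference mean to 1", {
  signals <- data.frame(
    signal = c(2, 4, 6), antiserum = "anti-D1", experiment = 1,
    strain = c("mut1", "WT", "mut2")
  )
  res <- blot_normalize(signals, "WT")
  expect_equal(res$scaled, c(0.5, 1, 1.5))
  expect_equal(res$normalized, c(0.5, 1, 1.5))

  equal <- data.frame(signal = rep(3, 4), antiserum = "a", experiment = 1,
                      strain = c("WT", "WT", "m", "m"))
  expect_equal(blot_normalize(equal, "WT")$normalized, rep(1, 4))

  # scaling one experiment's raw signals leaves its output unchanged
  two <- data.frame(
    signal = c(2, 4, 20, 40), antiserum = "a", experiment = c(1, 1, 2, 2),
    strain = c("WT", "m", "WT", "m")
  )
  res2 <- blot_normalize(two, "WT")
  expect_equal(res2$normalized[1:2], res2$normalized[3:4])

  expect_error(blot_normalize(two, "absent"), "absent")
  zero <- data.frame(signal = 0, antiserum = "a", experiment = 1, strain = "WT")
  expect_error(blot_normalize(zero, "WT"), "all-zero")
})

test_that("per-cell stoichiometry does the unit algebra exactly", {
  # unit sanity: 100% of 25 pg at 25 kDa -> 1000 amol
  expect_equal(abundance_per_cell(100, 25, 25)$amount_amol, 1000)
  # independent algebra: pg -> g -> mol -> amol
  oracle <- 0.0034 / 100 * 25 * 1e-12 / (12.5 * 1000) * 1e18
  res <- abundance_per_cell(0.0034, 25, 12.5, reference_amount_amol = 5.2)
  expect_equal(res$amount_amol, oracle, tolerance = 1e-12)
  expect_equal(res$amount_amol, 0.068, tolerance = 1e-12)
  expect_equal(res$fold_vs_reference, 5.2 / 0.068, tolerance = 1e-9)
  expect_error(abundance_per_cell(-1, 25, 12.5), "positive")
  expect_error(abundance_per_cell(0.003, 25, Inf), "positive")
})
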