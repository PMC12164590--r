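test_that("lane totals sum slices and are additive over disjoint windows", {
  cube <- profile_cube(list(
    P1 = list(WT = matrix(c(1, 2, 3), 1), mut = matrix(c(0, 0, 0), 1))
  ))
  totals <- lane_totals(cube)
  expect_equal(totals$total[totals$strain == "WT"], 6)
  expect_equal(totals$total[totals$strain == "mut"], 0)

  # additivity: window sums over slices 1 and 2..3 add to the lane total
  w1 <- sum(dplyr::filter(cube$data, strain == "WT", slice == 1)$intensity)
  w2 <- sum(dplyr::filter(cube$data, strain == "WT", slice >= 2)$intensity)
  expect_equal(w1 + w2, 6)
})

test_that("median-of-ratios factors match the hand-computed example", {
  # anchors a1 = (2, 8), a2 = (3, 12): references 4 and 6, factors (0.5, 2)
  totals <- expand.grid(protein_id = c("a1", "a2"), strain = c("s1", "s2"),
                        replicate = 1L, stringsAsFactors = FALSE)
  totals$total <- c(2, 3, 8, 12)
  cube <- lane_cube(totals)
  res <- size_factors(cube, c("a1", "a2"))
  expect_equal(unname(res$reference[c("a1", "a2")]), c(4, 6))
  expect_equal(res$factors$size_factor, c(0.5, 2))

  # after apply, anchor lane totals are equal across samples
  norm <- apply_size_factors(cube, res)
  nt <- lane_totals(norm)
  expect_equal(nt$total[nt$protein_id == "a1"], c(4, 4))
  expect_equal(nt$total[nt$protein_id == "a2"], c(6, 6))
})

test_that("identical samples give unit factors; a single anchor is exact", {
  cube <- grid_cube(proteins = c("a1", "P"), n_rep = 3)
  res <- size_factors(cube, "a1")
  expect_equal(res$factors$size_factor, rep(1, 6))

  totals <- expand.grid(protein_id = "a1", strain = c("s1", "s2"),
                        replicate = 1L, stringsAsFactors = FALSE)
  totals$total <- c(5, 20)
  res2 <- size_factors(lane_cube(totals), "a1")
  expect_equal(res2$factors$size_factor, c(5, 20) / 10)
})

test_that("anchors with a zero total are dropped; none usable is an error", {
  totals <- expand.grid(protein_id = c("a1", "a2"), strain = c("s1", "s2"),
                        replicate = 1L, stringsAsFactors = FALSE)
  totals$total <- c(2, 0, 8, 6)
  cube <- lane_cube(totals)
  expect_message(res <- size_factors(cube, c("a1", "a2")), "dropped: a2")
  expect_equal(res$anchors_used, "a1")
  expect_equal(res$anchors_dropped, "a2")

  totals$total <- c(0, 0, 8, 6)
  expect_error(suppressMessages(size_factors(lane_cube(totals), c("a1", "a2"))),
               "no usable anchors")
})

test_that("normalization recovers planted loading factors up to a gauge", {
  lf <- c(0.5, 1, 2, 0.5, 1, 2)
  cfg <- sim_config(seed = 4, noise_cv = 0, loading_factors = lf)
  sim <- simulate_dataset(demo_complex_specs(), cfg)
  res <- size_factors(sim$cube, atp_anchors())
  ratio <- res$factors$size_factor / lf
  expect_lt(max(ratio) - min(ratio), 1e-9)
  # geometric-mean gauge: all anchors usable -> factors multiply to 1
  expect_equal(exp(mean(log(res$factors$size_factor))), 1, tolerance = 1e-9)

  # idempotence: factors recomputed after applying are all ~1
  norm <- apply_size_factors(sim$cube, res)
  res2 <- size_factors(norm, atp_anchors())
  expect_equal(res2$factors$size_factor, rep(1, 6), tolerance = 1e-9)
})

test_that("applying factors validates coverage and positivity", {
  cube <- grid_cube()
  res <- size_factors(cube, "P1")
  res$factors$size_factor[1] <- -1
  expect_error(apply_size_factors(cube, res), "positive")

  res2 <- size_factors(cube, "P1")
  res2$factors <- res2$factors[-1, ]
  expect_error(apply_size_factors(cube, res2), "missing")
})
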