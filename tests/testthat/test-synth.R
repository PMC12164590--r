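test_that("expected profiles match the hand-computed discretized Gaussian", {
  # two states at slices 10 and 20 with equal abundance
  cx <- complex_spec("C", c(A = 2), list(
    assembly_state("s10", 10, 1.5, 30, 30),
    assembly_state("s20", 20, 1.5, 30, 30)
  ))
  truth <- build_truth(cx, sim_config(seed = 1))
  expected <- oracle_state_profile(36, 10, 1.5, 30, stoich = 2) +
    oracle_state_profile(36, 20, 1.5, 30, stoich = 2)
  expect_equal(truth$expected["A", "WT", ], expected, tolerance = 1e-12)
  # lane sum = stoichiometry x total abundance
  expect_equal(sum(truth$expected["A", "WT", ]), 2 * 60, tolerance = 1e-12)
})

test_that("degenerate peaks and absent states behave as limits demand", {
  cx <- complex_spec("C", c(A = 1, B = 1), list(
    assembly_state("delta", 12, 0, 10, 10),
    assembly_state("mut_absent", 20, 1, 8, 0, members = "B")
  ))
  truth <- build_truth(cx, sim_config(seed = 1))
  # width 0: all state mass lands in the peak slice
  a_wt <- truth$expected["A", "WT", ]
  expect_equal(a_wt[12], 10)
  expect_equal(sum(a_wt[-12]), 0)
  # subunit unique to a state with zero test-strain abundance: flat zero
  b_extra <- truth$expected["B", "psb28", ] - truth$expected["A", "psb28", ]
  expect_equal(unname(b_extra), rep(0, 36), tolerance = 1e-12)
})

test_that("shared protein ids across complexes are rejected", {
  c1 <- complex_spec("C1", c(A = 1), list(assembly_state("s", 5, 1, 1, 1)))
  c2 <- complex_spec("C2", c(A = 1), list(assembly_state("s", 9, 1, 1, 1)))
  expect_error(build_truth(list(c1, c2), sim_config(seed = 1)), "shared")
})

test_that("simulation is exact without noise and bit-identical per seed", {
  specs <- demo_complex_specs()
  cfg0 <- sim_config(seed = 5, noise_cv = 0, loading_factors = 1)
  truth <- build_truth(specs, cfg0)
  cube <- simulate_cube(truth)
  for (p in c("AtpA", "PsbA")) {
    for (s in c("WT", "psb28")) {
      vals <- dplyr::filter(cube$data, protein_id == p, strain == s,
                            replicate == 2) |>
        dplyr::arrange(slice)
      expect_equal(vals$intensity, unname(truth$expected[p, s, ]),
                   tolerance = 1e-12)
    }
  }

  cfg <- sim_config(seed = 42, noise_cv = 0.25)
  sim1 <- simulate_dataset(specs, cfg)
  sim2 <- simulate_dataset(specs, cfg)
  expect_identical(sim1$cube$data, sim2$cube$data)
  expect_identical(sim1$cube$proteins, sim2$cube$proteins)
})

test_that("lane sums conserve loading x expected mass without noise", {
  specs <- demo_complex_specs()
  lf <- c(0.5, 1, 2, 0.5, 1, 2)
  cfg <- sim_config(seed = 3, noise_cv = 0, loading_factors = lf)
  sim <- simulate_dataset(specs, cfg)
  totals <- lane_totals(sim$cube)
  truth <- sim$truth
  for (i in seq_len(nrow(truth$loading))) {
    s <- truth$loading$strain[i]; r <- truth$loading$replicate[i]
    got <- dplyr::filter(totals, protein_id == "PetA", strain == s,
                         replicate == r)$total
    expect_equal(got,
                 truth$loading$loading_factor[i] * sum(truth$expected["PetA", s, ]),
                 tolerance = 1e-9)
  }
})

test_that("raising the detection floor never adds nonzero cells", {
  specs <- demo_complex_specs()
  floors <- c(0, 0.01, 0.1, 1)
  nonzero <- vapply(floors, function(f) {
    cfg <- sim_config(seed = 9, noise_cv = 0.2, detection_floor = f)
    sum(simulate_dataset(specs, cfg)$cube$data$intensity > 0)
  }, numeric(1))
  expect_true(all(diff(nonzero) <= 0))
})

test_that("log-normal noise has the configured spread and unit mean", {
  cx <- complex_spec("C", c(A = 1),
                     list(assembly_state("s", 18, 0, 1, 1)))
  cfg <- sim_config(seed = 2, noise_cv = 0.2, n_replicates = 4000)
  vals <- simulate_dataset(cx, cfg)$cube$data
  vals <- vals$intensity[vals$slice == 18]
  expect_equal(mean(vals), 1, tolerance = 0.02)
  expect_equal(sd(vals) / mean(vals), 0.2, tolerance = 0.05)
})

test_that("peptide tables sum to the protein values with the stated counts", {
  cfg <- sim_config(seed = 13, noise_cv = 0.2)
  sim <- simulate_dataset(demo_complex_specs()[1:2], cfg)
  truth <- build_truth(demo_complex_specs()[1:2], cfg)
  cube <- simulate_cube(truth, peptides = TRUE)
  pep <- attr(cube, "peptides")
  sums <- dplyr::summarise(pep, total = sum(intensity),
                           .by = c("protein_id", "strain", "replicate", "slice"))
  merged <- dplyr::left_join(cube$data, sums,
                             by = c("protein_id", "strain", "replicate", "slice"))
  expect_equal(merged$total, merged$intensity, tolerance = 1e-9)
  counts <- dplyr::summarise(pep, n = dplyr::n_distinct(peptide_id),
                             .by = "protein_id")
  meta <- cube$proteins
  expect_equal(counts$n[match(meta$protein_id, counts$protein_id)],
               meta$peptide_count)
})

test_that("written datasets round-trip and record the planted factor", {
  cfg <- sim_config(seed = 21, noise_cv = 0.1, planted = planted_factor())
  sim <- simulate_dataset(screen_scenario_specs(5), cfg)
  dir <- withr::local_tempdir()
  write_dataset(sim$cube, sim$truth, dir)
  back <- read_long_tsv(file.path(dir, "intensities.tsv"))
  expect_equal(back$data, sim$cube$data)
  truth_file <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth_file$planted_factor, "CAND1")
  expect_equal(truth_file$loading_factors, rep(1, 6))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(sim_config(loading_factors = c(1, 0)), "loading factors")
  expect_error(sim_config(n_replicates = 0))
  expect_error(build_truth(
    complex_spec("C", c(A = 1), list(assembly_state("s", 40, 1, 1, 1))),
    sim_config(seed = 1)
  ), "outside the lane")
})
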