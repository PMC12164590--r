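test_that("window sums are per-strain, additive, and lane-consistent", {
  cube <- profile_cube(list(
    P1 = list(WT = rbind(c(1, 2, 3), c(1, 2, 3)),
              mut = rbind(c(2, 4, 6), c(2, 4, 6)))
  ))
  full <- window_sums(cube, "P1", band_window("all", 1, 3),
                      reference = "WT", test = "mut")
  lane <- window_sums(cube, "P1", reference = "WT", test = "mut")
  expect_equal(full, lane)
  expect_equal(unname(lane), c(12, 24))

  w1 <- window_sums(cube, "P1", band_window("a", 1, 1),
                    reference = "WT", test = "mut")
  w2 <- window_sums(cube, "P1", band_window("b", 2, 3),
                    reference = "WT", test = "mut")
  expect_equal(w1 + w2, lane)

  # protein with no mass in a window
  zero <- profile_cube(list(
    P1 = list(WT = rbind(c(1, 0, 0)), mut = rbind(c(1, 0, 0)))
  ))
  expect_equal(unname(window_sums(zero, "P1", band_window("t", 2, 3),
                                  reference = "WT", test = "mut")),
               c(0, 0))
})

test_that("the detection boundary is strictly-below-threshold", {
  pol <- detection_policy(0.0005)
  expect_false(is_detected(0.4, 1000, pol))   # 0.04% < 0.05%
  expect_true(is_detected(0.5, 1000, pol))    # exactly 0.05% counts
  expect_true(is_detected(1e-9, 1000, detection_policy(0)))
  expect_error(is_detected(1, 0, pol), "> 0")
  expect_error(detection_policy(1), "\\[0, 1\\)")
})

test_that("raising the threshold never turns not-detected into detected", {
  sums <- c(0, 0.2, 0.5, 3, 10)
  thresholds <- c(0, 1e-4, 5e-4, 1e-3, 1e-2)
  detected <- sapply(thresholds, function(th) {
    is_detected(sums, 1000, detection_policy(th))
  })
  for (i in seq_len(nrow(detected))) {
    expect_true(all(diff(as.integer(detected[i, ])) <= 0))
  }
})

test_that("identical strains give unit ratios everywhere defined", {
  cube <- grid_cube(proteins = c("P1", "P2"), n_rep = 3, n_slices = 36,
                    intensity = 2)
  tab <- ratio_table(cube, reference = "WT", test = "mut")
  expect_true(all(tab$ratio[!is.na(tab$ratio)] == 1))
})

test_that("planted fold-changes are recovered exactly without noise", {
  # RCII-window state 10x higher in the test strain; a second protein only
  # present in the reference strain
  specs <- list(
    complex_spec("C", c(X = 1), list(
      assembly_state("rc", 22, 0.6, 3, 30)
    )),
    complex_spec("W", c(Y = 1), list(
      assembly_state("wtonly", 22, 0.6, 5, 0)
    )),
    complex_spec("A", c(anchor = 1),
                 list(assembly_state("s", 10, 1, 50, 50)))
  )
  sim <- simulate_dataset(specs, sim_config(seed = 1, noise_cv = 0))
  tab <- ratio_table(sim$cube, policy = detection_policy(0.0005))
  x_rc <- tab[tab$protein_id == "X" & tab$scope == "RCII", ]
  expect_equal(x_rc$ratio, 10, tolerance = 1e-9)
  y_rc <- tab[tab$protein_id == "Y" & tab$scope == "RCII", ]
  expect_true(is.na(y_rc$ratio))
  expect_equal(y_rc$flag, "nd")
})

test_that("scaling the test strain scales all defined ratios", {
  cfg <- sim_config(seed = 10, noise_cv = 0.1)
  sim <- simulate_dataset(demo_complex_specs(), cfg)
  tab1 <- ratio_table(sim$cube)
  scaled <- sim$cube
  scaled$data$intensity[scaled$data$strain == "psb28"] <-
    scaled$data$intensity[scaled$data$strain == "psb28"] * 3
  tab2 <- ratio_table(scaled)
  both <- !is.na(tab1$ratio) & !is.na(tab2$ratio)
  expect_gt(sum(both), 0)
  expect_equal(tab2$ratio[both], 3 * tab1$ratio[both], tolerance = 1e-9)
})

test_that("complex medians reproduce the bundled subunit-ratio table", {
  path <- system.file("extdata", "psb28_subunit_ratios.tsv",
                      package = "comigrate")
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  ratios <- tibble::tibble(protein_id = tab$subunit, ratio = tab$ratio)
  med <- function(group, exclude = NULL) {
    members <- tab$subunit[tab$group == group]
    complex_median_ratio(ratios, members, name = group,
                         exclude = exclude)$median_ratio
  }
  expect_equal(med("Cyt b6f"), 1.87)
  expect_equal(med("OEC"), 0.45)
  expect_equal(med("ATP synthase"), 1.03)
  expect_equal(med("LHCII"), 0.55)
  # non-canonical member excluded from the core median
  expect_equal(med("PSII core", exclude = "PBA1"), 0.15)
})

test_that("complex summaries track exclusions and degenerate inputs", {
  ratios <- tibble::tibble(protein_id = c("A", "B", "C"),
                           ratio = c(2, NA, 4))
  s <- complex_median_ratio(ratios, c("A", "B", "C", "D"), name = "cx")
  expect_equal(s$median_ratio, 3)
  expect_setequal(s$members_used, c("A", "C"))
  expect_match(s$excluded[["B"]], "not detected")
  expect_match(s$excluded[["D"]], "no ratio")

  single <- complex_median_ratio(ratios, "A")
  expect_equal(single$median_ratio, 2)

  expect_error(complex_median_ratio(ratios, "B"), "no member")

  rounded <- tibble::tibble(protein_id = c("A", "B"), ratio = c(0.114, 0.129))
  expect_equal(complex_median_ratio(rounded, c("A", "B"),
                                    round_digits = 2)$median_ratio,
               mean(c(0.11, 0.13)))
})
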