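#' Describe one assembly state of a complex
#'
#' An assembly state is a population of a complex (or of a module of it)
#' that migrates as one approximately Gaussian peak along the BN-PAGE lane:
#' e.g. PSII supercomplexes, dimers, monomers/RC47, the RCII intermediate, or
#' a preassembled CP43 module. Each state carries its own abundance in the
#' reference and the test strain, so strain-specific accumulation of
#' intermediates (including mutant-only intermediates) is expressed directly.
#'
#' @param name State label, unique within its complex.
#' @param peak_slice Slice at which the state's migration peak sits
#'   (integer, within the lane).
#' @param peak_width Standard deviation of the discretized Gaussian peak, in
#'   slices (> 0; values below 1e-8 collapse to a delta peak).
#' @param abundance_ref,abundance_test State abundance (arbitrary ion
#'   intensity units, >= 0) in the reference and test strain.
#' @param members Optional character vector: the subset of the complex's
#'   subunits present in this state (e.g. only D1/D2/PsbE/PsbF in RCII).
#'   `NULL` means all subunits.
#' @return An `assembly_state` object.
#' @export
assembly_state <- function(name, peak_slice, peak_width,
                           abundance_ref, abundance_test, members = NULL) {
  stopifnot(length(name) == 1, is.numeric(peak_slice), is.numeric(peak_width))
  if (peak_width < 0) stop("peak_width must be >= 0", call. = FALSE)
  if (!is.finite(abundance_ref) || !is.finite(abundance_test) ||
      abundance_ref < 0 || abundance_test < 0) {
    stop("state abundances must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(name = as.character(name), peak_slice = as.integer(peak_slice),
         peak_width = as.double(peak_width),
         abundance_ref = as.double(abundance_ref),
         abundance_test = as.double(abundance_test),
         members = members),
    class = "assembly_state"
  )
}

#' Describe a protein complex for the simulator
#'
#' @param name Complex label.
#' @param subunits Named numeric vector: protein ids with their (positive)
#'   stoichiometry weights.
#' @param states List of [assembly_state()] objects with unique names; each
#'   state's `members` must be a subset of `names(subunits)`.
#' @return A `complex_spec` object.
#' @export
complex_spec <- function(name, subunits, states) {
  if (length(subunits) < 1 || is.null(names(subunits)) ||
      any(!nzchar(names(subunits)))) {
    stop("subunits must be a named numeric vector with >= 1 entry",
         call. = FALSE)
  }
  if (any(!is.finite(subunits)) || any(subunits <= 0)) {
    stop("stoichiometry weights must be positive", call. = FALSE)
  }
  if (anyDuplicated(names(subunits))) {
    stop("duplicate subunit id within complex ", name, call. = FALSE)
  }
  states <- if (inherits(states, "assembly_state")) list(states) else states
  stopifnot(length(states) >= 1)
  state_names <- vapply(states, `[[`, "", "name")
  if (anyDuplicated(state_names)) {
    stop("state names must be unique within complex ", name, call. = FALSE)
  }
  for (st in states) {
    if (!inherits(st, "assembly_state")) stop("states must be assembly_state objects", call. = FALSE)
    if (!is.null(st$members) && !all(st$members %in% names(subunits))) {
      stop("state ", st$name, " of complex ", name,
           " references unknown subunit(s)", call. = FALSE)
    }
  }
  structure(
    list(name = as.character(name), subunits = subunits,
         states = stats::setNames(states, state_names)),
    class = "complex_spec"
  )
}

#' Describe a planted candidate assembly factor
#'
#' The planted factor emulates the screen's target class: a protein that is
#' present in both strains as an unassembled (low molecular mass) pool but
#' comigrates with a named assembly-intermediate state in the test strain
#' only. Its identity is recorded in the ground truth so screen sensitivity
#' can be measured.
#'
#' @param protein_id Id of the planted protein.
#' @param comigrate_with Name of the assembly state (in any complex of the
#'   simulation) whose peak the factor joins in the test strain.
#' @param abundance Test-strain abundance of the comigrating pool.
#' @param background_abundance Abundance of the unassembled pool, identical
#'   in both strains (keeps the factor detectable in the reference lane).
#' @param background_slice,background_width Peak position/width of the
#'   unassembled pool.
#' @param peptide_count Number of peptides to report for the factor.
#' @return A `planted_factor` object.
#' @export
planted_factor <- function(protein_id = "CAND1", comigrate_with = "RCII",
                           abundance = 30, background_abundance = 20,
                           background_slice = 34, background_width = 0.8,
                           peptide_count = 4) {
  stopifnot(abundance >= 0, background_abundance >= 0, peptide_count >= 0)
  structure(
    list(protein_id = protein_id, comigrate_with = comigrate_with,
         abundance = abundance, background_abundance = background_abundance,
         background_slice = as.integer(background_slice),
         background_width = background_width,
         peptide_count = as.integer(peptide_count)),
    class = "planted_factor"
  )
}

#' Simulation configuration
#'
#' Defines the experimental design the generator emulates: a two-strain
#' BN-PAGE complexome experiment with 36 slices per lane and 3 biological
#' replicates per strain, per-sample loading factors, multiplicative
#' log-normal intensity noise, and a hard detection floor.
#'
#' @param n_slices Gel slices per lane.
#' @param n_replicates Biological replicates per strain (>= 1).
#' @param strains Length-2 character vector `c(reference, test)`.
#' @param loading_factors Per-sample multiplicative loading factors (> 0),
#'   recycled to the number of samples; samples are ordered reference
#'   replicates first, then test replicates.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise (>= 0). The noise has mean 1, so expected intensities are
#'   unbiased.
#' @param detection_floor Absolute intensity below which a simulated value is
#'   zeroed ("not detected").
#' @param dropout_prob Probability of stochastically zeroing a cell on top of
#'   the floor (off by default).
#' @param nonproteotypic_rate Fraction of non-planted proteins flagged as
#'   identified only by shared peptides.
#' @param seed Integer seed; every random draw of the simulator flows from
#'   this single stream.
#' @param planted Optional [planted_factor()].
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_slices = 36, n_replicates = 3,
                       strains = c("WT", "psb28"),
                       loading_factors = 1, noise_cv = 0.2,
                       detection_floor = 0, dropout_prob = 0,
                       nonproteotypic_rate = 0, seed = 1, planted = NULL) {
  stopifnot(n_slices >= 1, n_replicates >= 1, length(strains) == 2)
  if (any(loading_factors <= 0)) stop("loading factors must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (detection_floor < 0) stop("detection_floor must be >= 0", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("dropout_prob must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted) && !inherits(planted, "planted_factor")) {
    stop("planted must be a planted_factor", call. = FALSE)
  }
  n_samples <- 2L * n_replicates
  structure(
    list(n_slices = as.integer(n_slices),
         n_replicates = as.integer(n_replicates),
         strains = as.character(strains),
         loading_factors = rep_len(as.double(loading_factors), n_samples),
         noise_cv = as.double(noise_cv),
         detection_floor = as.double(detection_floor),
         dropout_prob = as.double(dropout_prob),
         nonproteotypic_rate = as.double(nonproteotypic_rate),
         seed = as.integer(seed), planted = planted),
    class = "sim_config"
  )
}

# Discretized Gaussian migration peak: evaluated at slice centers 1..n and
# renormalized to sum 1, so edge truncation does not lose state mass and
# lane sums stay interpretable. width below 1e-8 degenerates to a delta.
.peak_weights <- function(n, peak_slice, peak_width) {
  if (peak_width < 1e-8) {
    w <- numeric(n)
    w[peak_slice] <- 1
    return(w)
  }
  w <- stats::dnorm(seq_len(n), mean = peak_slice, sd = peak_width)
  w / sum(w)
}

#' Build the noise-free ground truth of a simulation
#'
#' Computes, deterministically, the expected intensity of every protein in
#' every strain at every slice: the sum over the assembly states containing
#' the protein of stoichiometry x state abundance x discretized Gaussian
#' peak weight. The planted factor (if any) is materialized as an extra
#' single-subunit complex with an unassembled pool in both strains and a
#' test-strain-only pool comigrating with its target state.
#'
#' @param complex_specs List of [complex_spec()] objects. A protein id may
#'   appear in only one complex.
#' @param config A [sim_config()].
#' @return A `ground_truth` object: list with `expected` (3-d array protein x
#'   strain x slice), `specs`, `config`, `proteins` (metadata tibble),
#'   `loading` (per-sample factor tibble) and `planted_id`.
#' @export
build_truth <- function(complex_specs, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(complex_specs, "complex_spec")) complex_specs <- list(complex_specs)
  for (cx in complex_specs) {
    if (!inherits(cx, "complex_spec")) stop("complex_specs must be complex_spec objects", call. = FALSE)
    for (st in cx$states) {
      if (st$peak_slice < 1 || st$peak_slice > config$n_slices) {
        stop("state ", st$name, " of ", cx$name, " peaks outside the lane",
             call. = FALSE)
      }
    }
  }

  planted_id <- NA_character_
  if (!is.null(config$planted)) {
    pf <- config$planted
    target <- NULL
    for (cx in complex_specs) {
      if (pf$comigrate_with %in% names(cx$states)) {
        target <- cx$states[[pf$comigrate_with]]
        break
      }
    }
    if (is.null(target)) {
      stop("planted factor targets unknown state ", pf$comigrate_with,
           call. = FALSE)
    }
    states <- list(
      assembly_state("unassembled", pf$background_slice, pf$background_width,
                     pf$background_abundance, pf$background_abundance),
      assembly_state(paste0("with_", pf$comigrate_with), target$peak_slice,
                     target$peak_width, 0, pf$abundance)
    )
    complex_specs <- c(complex_specs,
                       list(complex_spec(pf$protein_id,
                                         stats::setNames(1, pf$protein_id),
                                         states)))
    planted_id <- pf$protein_id
  }

  all_ids <- unlist(lapply(complex_specs, function(cx) names(cx$subunits)))
  if (anyDuplicated(all_ids)) {
    stop("protein id(s) shared between complexes: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }

  ids <- sort(unique(all_ids))
  expected <- array(
    0, dim = c(length(ids), 2L, config$n_slices),
    dimnames = list(protein_id = ids, strain = config$strains, slice = NULL)
  )
  complex_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (cx in complex_specs) {
    complex_of[names(cx$subunits)] <- cx$name
    for (st in cx$states) {
      w <- .peak_weights(config$n_slices, st$peak_slice, st$peak_width)
      members <- if (is.null(st$members)) names(cx$subunits) else st$members
      for (p in members) {
        stoich <- cx$subunits[[p]]
        expected[p, 1, ] <- expected[p, 1, ] + stoich * st$abundance_ref * w
        expected[p, 2, ] <- expected[p, 2, ] + stoich * st$abundance_test * w
      }
    }
  }

  loading <- tibble::tibble(
    strain = rep(config$strains, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = 2),
    loading_factor = config$loading_factors
  )
  proteins <- tibble::tibble(
    protein_id = ids, gene = ids,
    complex = unname(complex_of[ids]),
    category = ifelse(ids == planted_id & !is.na(planted_id),
                      "planted factor", "simulated")
  )

  structure(
    list(expected = expected, specs = complex_specs, config = config,
         proteins = proteins, loading = loading, planted_id = planted_id),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$proteins), " proteins, strains ",
      paste(x$config$strains, collapse = "/"), ", ",
      x$config$n_slices, " slices",
      if (!is.na(x$planted_id)) paste0(", planted factor ", x$planted_id),
      "\n", sep = "")
  invisible(x)
}

#' Simulate an intensity cube from a ground truth
#'
#' Every replicate value is the expected value times the sample's loading
#' factor times a mean-one multiplicative log-normal noise term with the
#' configured coefficient of variation; values below the detection floor are
#' zeroed. All randomness flows from `config$seed` through one RNG stream in
#' a fixed cell order, so the same seed yields a bit-identical dataset.
#'
#' @param truth A [build_truth()] result.
#' @param peptides If `TRUE`, also generate a per-peptide long table whose
#'   per-protein sums equal the protein values exactly; returned as
#'   attribute `"peptides"` of the cube.
#' @return An [intensity_cube()] carrying peptide counts and proteotypic
#'   flags in its protein metadata.
#' @export
simulate_cube <- function(truth, peptides = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  ids <- dimnames(truth$expected)$protein_id
  n_p <- length(ids); n_s <- nrow(truth$loading); n_k <- cfg$n_slices

  set.seed(cfg$seed)

  # expected value for every (protein, sample, slice) cell, canonical order:
  # protein-major, then sample (reference replicates first), then slice
  strain_idx <- match(truth$loading$strain, cfg$strains)
  exp_cells <- numeric(n_p * n_s * n_k)
  pos <- 1L
  for (ip in seq_len(n_p)) {
    for (is in seq_len(n_s)) {
      exp_cells[pos:(pos + n_k - 1L)] <-
        truth$expected[ip, strain_idx[is], ] * truth$loading$loading_factor[is]
      pos <- pos + n_k
    }
  }

  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- stats::rlnorm(length(exp_cells), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
    values <- exp_cells * noise
  } else {
    values <- exp_cells
  }
  if (cfg$dropout_prob > 0) {
    values[stats::runif(length(values)) < cfg$dropout_prob] <- 0
  }
  if (cfg$detection_floor > 0) {
    values[values < cfg$detection_floor] <- 0
  }

  data <- tibble::tibble(
    protein_id = rep(ids, each = n_s * n_k),
    strain = rep(rep(truth$loading$strain, each = n_k), times = n_p),
    replicate = rep(rep(truth$loading$replicate, each = n_k), times = n_p),
    slice = rep(seq_len(n_k), times = n_p * n_s),
    intensity = values
  )

  # protein metadata: peptide counts and proteotypic flags come from the same
  # stream (planted factor keeps its configured count and is proteotypic)
  peptide_count <- 3L + stats::rpois(n_p, 3)
  proteotypic <- stats::runif(n_p) >= cfg$nonproteotypic_rate
  if (!is.na(truth$planted_id)) {
    i <- match(truth$planted_id, ids)
    peptide_count[i] <- cfg$planted$peptide_count
    proteotypic[i] <- TRUE
  }
  proteins <- dplyr::mutate(truth$proteins,
                            peptide_count = peptide_count,
                            proteotypic = proteotypic)

  cube <- intensity_cube(data, proteins = proteins, n_slices = n_k)

  if (peptides) {
    # fixed per-protein peptide proportions so peptide sums reproduce the
    # protein value in every cell
    pep <- vector("list", n_p)
    for (ip in seq_len(n_p)) {
      m <- peptide_count[ip]
      g <- stats::rgamma(m, shape = 1)
      prop <- g / sum(g)
      rows <- dplyr::filter(cube$data, .data$protein_id == ids[ip])
      pep[[ip]] <- tidyr::expand_grid(rows, peptide = seq_len(m)) |>
        dplyr::mutate(
          peptide_id = paste0(.data$protein_id, "_pep", .data$peptide),
          intensity = .data$intensity * prop[.data$peptide]
        ) |>
        dplyr::select("peptide_id", "protein_id", "strain", "replicate",
                      "slice", "intensity")
    }
    attr(cube, "peptides") <- dplyr::bind_rows(pep)
  }
  cube
}

#' Build ground truth and simulate in one call
#'
#' @inheritParams build_truth
#' @inheritParams simulate_cube
#' @return List with elements `cube` and `truth`.
#' @export
simulate_dataset <- function(complex_specs, config, peptides = FALSE) {
  truth <- build_truth(complex_specs, config)
  list(cube = simulate_cube(truth, peptides = peptides), truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `intensities.tsv` (long TSV dialect, see [read_long_tsv()]),
#' `annotations.tsv`, and `truth.yaml` recording the planted parameters
#' (loading factors, planted factor id, per-state abundances). The intensity
#' file round-trips exactly through [read_long_tsv()].
#'
#' @param cube An [intensity_cube()].
#' @param truth The matching `ground_truth` (optional).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cube, truth = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_long_tsv(cube, file.path(dir, "intensities.tsv"))
  readr::write_tsv(cube$proteins[, c("protein_id", "gene", "complex", "category")],
                   file.path(dir, "annotations.tsv"), progress = FALSE)
  if (!is.null(truth)) {
    states <- lapply(truth$specs, function(cx) {
      lapply(unname(cx$states), function(st) {
        list(complex = cx$name, state = st$name, peak_slice = st$peak_slice,
             peak_width = st$peak_width, abundance_ref = st$abundance_ref,
             abundance_test = st$abundance_test)
      })
    })
    yaml::write_yaml(
      list(
        seed = truth$config$seed,
        strains = as.list(stats::setNames(truth$config$strains,
                                          c("reference", "test"))),
        noise_cv = truth$config$noise_cv,
        loading_factors = truth$loading$loading_factor,
        planted_factor = if (is.na(truth$planted_id)) NULL else truth$planted_id,
        states = unlist(states, recursive = FALSE)
      ),
      file.path(dir, "truth.yaml")
    )
  }
  invisible(dir)
}

#' Demonstration thylakoid complexome specification
#'
#' A compact model of the thylakoid membrane complexome of a PSII-assembly
#' mutant versus wild type: an 8-subunit ATP synthase anchor complex (equal
#' abundance in both strains), the cytochrome b6f complex (overaccumulating
#' in the mutant), PSII with its assembly states (supercomplexes, dimers,
#' monomers/RC47 collapsing in the mutant; RCII and the CP43/D1 modules
#' accumulating in the mutant only), PSI-LHCI, and free LHCII. Peak
#' positions follow the default band windows of [psii_band_windows()].
#'
#' @return List of [complex_spec()] objects.
#' @export
demo_complex_specs <- function() {
  atp_ids <- c("AtpA", "AtpB", "ATPC", "ATPD", "AtpE", "AtpF", "ATPG", "atpI")
  psii_ids <- c("PsbA", "PsbB", "PsbC", "PsbD", "PsbE", "PsbF", "PsbH",
                "PsbJ", "PsbL")
  list(
    complex_spec("ATP synthase", stats::setNames(rep(1, 8), atp_ids),
                 list(assembly_state("ATPase", 16, 1.0, 600, 600))),
    complex_spec("Cyt b6f",
                 stats::setNames(rep(1, 6),
                                 c("PetA", "PetB", "PETC", "PetD", "PETM",
                                   "PETO")),
                 list(assembly_state("b6f dimer", 19, 1.0, 150, 280))),
    complex_spec("PSII", stats::setNames(rep(1, 9), psii_ids),
                 list(
                   assembly_state("SC", 9, 1.2, 400, 4),
                   assembly_state("Dimers", 14, 0.9, 250, 15),
                   assembly_state("Monomers/RC47", 17, 0.8, 150, 40),
                   assembly_state("RCII", 22, 0.7, 1, 35,
                                  members = c("PsbA", "PsbD", "PsbE", "PsbF")),
                   assembly_state("CP43_mod", 25, 0.7, 1, 12,
                                  members = "PsbC"),
                   assembly_state("D1_mod", 29, 0.8, 5, 11,
                                  members = c("PsbA", "PsbE", "PsbF"))
                 )),
    complex_spec("PSI",
                 stats::setNames(rep(1, 7),
                                 c("PsaA", "PsaB", "PsaC", "PSAD", "LHCA1",
                                   "LHCA2", "LHCA3")),
                 list(assembly_state("PSI-LHCI", 10, 1.0, 300, 250))),
    complex_spec("LHCII",
                 stats::setNames(rep(1, 3), c("LHCBM1", "LHCB4", "LHCB5")),
                 list(assembly_state("LHCII trimer", 31, 1.0, 500, 275)))
  )
}

#' Null proteins for calibration studies
#'
#' Generates `n` unrelated single-subunit "complexes" with identical
#' abundance in both strains, peak positions cycling over the lane and a
#' range of peak widths — the null background against which type-I error and
#' screen specificity are measured. Deterministic (no RNG).
#'
#' @param n Number of null proteins.
#' @param abundance Lane abundance of each protein (both strains).
#' @param n_slices Lane length used to place the peaks.
#' @return List of [complex_spec()] objects.
#' @export
null_complex_specs <- function(n, abundance = 50, n_slices = 36) {
  lapply(seq_len(n), function(i) {
    id <- sprintf("NULL%04d", i)
    peak <- 2L + ((i * 7L) %% (n_slices - 2L))
    width <- 0.5 + 0.3 * (i %% 4)
    complex_spec(id, stats::setNames(1, id),
                 list(assembly_state("free", peak, width, abundance, abundance)))
  })
}

#' Complex specification for screen benchmarking
#'
#' The demonstration thylakoid complexome plus `n_null` null proteins; meant
#' to be simulated with a [sim_config()] whose `planted` slot carries a
#' [planted_factor()] comigrating with RCII in the test strain only.
#'
#' @param n_null Number of null background proteins.
#' @return List of [complex_spec()] objects.
#' @export
screen_scenario_specs <- function(n_null = 100) {
  c(demo_complex_specs(), null_complex_specs(n_null))
}
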