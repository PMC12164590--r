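#' Criteria of the comigration candidate screen
#'
#' A candidate early-assembly factor must (a) be detected (positive lane sum)
#' in at least `min_replicates_detected` replicates of each strain (or of the
#' test strain only, if `require_reference_detection = FALSE`), (b) be
#' quantified with at least `min_peptides` peptides, (c) in at least one
#' screened band window be detected in the test strain but not in the
#' reference strain under the detection policy, and (d) — if
#' `require_band_significance` — show a raw band-test p-value below
#' `p_threshold` in such a window.
#'
#' @param windows Names of the screened band windows (defaults: the PSII
#'   monomers/RC47 and RCII windows, where early intermediates run).
#' @param min_replicates_detected Required replicates with a positive lane
#'   sum, per strain.
#' @param min_peptides Required peptide count.
#' @param require_band_significance Require a significant band test in a
#'   qualifying window?
#' @param p_threshold Raw p-value threshold of the band test.
#' @param require_reference_detection Apply the replicate-detection rule to
#'   the reference strain too (the default) or only to the test strain.
#' @param policy [detection_policy()] used for window detection calls.
#' @return A `screen_criteria` object.
#' @export
screen_criteria <- function(windows = c("Monomers/RC47", "RCII"),
                            min_replicates_detected = 3,
                            min_peptides = 3,
                            require_band_significance = TRUE,
                            p_threshold = 0.05,
                            require_reference_detection = TRUE,
                            policy = detection_policy()) {
  stopifnot(length(windows) >= 1, min_replicates_detected >= 0,
            min_peptides >= 0, p_threshold > 0, p_threshold <= 1,
            inherits(policy, "detection_policy"))
  structure(
    list(windows = windows,
         min_replicates_detected = as.integer(min_replicates_detected),
         min_peptides = as.integer(min_peptides),
         require_band_significance = isTRUE(require_band_significance),
         p_threshold = p_threshold,
         require_reference_detection = isTRUE(require_reference_detection),
         policy = policy),
    class = "screen_criteria"
  )
}

#' Replicates in which a protein was detected
#'
#' Counts the replicates of one strain in which the protein has a positive
#' lane sum.
#'
#' @param cube An [intensity_cube()].
#' @param protein Protein id.
#' @param strain Strain label.
#' @return Integer in `[0, n_replicates]`.
#' @export
replicate_detection <- function(cube, protein, strain) {
  stopifnot(inherits(cube, "intensity_cube"))
  sums <- dplyr::filter(cube$data, .data$protein_id == protein,
                        .data$strain == !!strain) |>
    dplyr::summarise(total = sum(.data$intensity), .by = "replicate")
  sum(sums$total > 0)
}

#' Flag candidate assembly factors by mutant-specific comigration
#'
#' Applies the screen criteria to every protein of a normalized cube and
#' reports, for each, the per-window detection calls, band-test p-values,
#' the verdict, and — for rejected proteins — every violated criterion.
#'
#' @param cube A normalized [intensity_cube()] with peptide counts in its
#'   metadata.
#' @param criteria A [screen_criteria()].
#' @param windows Named list of known [band_window()]s.
#' @inheritParams welch_lane_test
#' @return Tibble with one row per protein: `protein_id`, `peptide_count`,
#'   `reps_ref`, `reps_test`, per-window columns
#'   `det_ref_<w>`/`det_test_<w>`/`p_<w>`, `qualifying_windows`, `candidate`,
#'   `reasons` (semicolon-separated failed criteria, empty for candidates).
#' @export
flag_candidates <- function(cube, criteria = screen_criteria(),
                            windows = psii_band_windows(),
                            reference = NULL, test = NULL) {
  stopifnot(inherits(cube, "intensity_cube"),
            inherits(criteria, "screen_criteria"))
  roles <- strain_roles(cube, reference, test)
  ids <- cube_proteins(cube)
  totals <- strain_totals(cube)

  # replicate detection per strain
  lane <- lane_totals(cube) |>
    dplyr::summarise(n_det = sum(.data$total > 0),
                     .by = c("protein_id", "strain")) |>
    tidyr::pivot_wider(names_from = "strain", values_from = "n_det",
                       values_fill = 0)
  reps_ref <- lane[[roles[["reference"]]]][match(ids, lane$protein_id)]
  reps_test <- lane[[roles[["test"]]]][match(ids, lane$protein_id)]

  out <- tibble::tibble(
    protein_id = ids,
    peptide_count = cube$proteins$peptide_count[match(ids, cube$proteins$protein_id)],
    reps_ref = reps_ref, reps_test = reps_test
  )

  qualifying <- matrix(FALSE, nrow = length(ids), ncol = length(criteria$windows),
                       dimnames = list(ids, criteria$windows))
  for (wname in criteria$windows) {
    w <- .resolve_window(wname, windows, cube$n_slices)
    wsums <- dplyr::filter(cube$data, .data$slice >= w$lo, .data$slice <= w$hi) |>
      dplyr::summarise(total = sum(.data$intensity),
                       .by = c("protein_id", "strain")) |>
      tidyr::pivot_wider(names_from = "strain", values_from = "total",
                         values_fill = 0)
    s_ref <- wsums[[roles[["reference"]]]][match(ids, wsums$protein_id)]
    s_test <- wsums[[roles[["test"]]]][match(ids, wsums$protein_id)]
    det_ref <- is_detected(s_ref, totals[[roles[["reference"]]]], criteria$policy)
    det_test <- is_detected(s_test, totals[[roles[["test"]]]], criteria$policy)
    bt <- band_test(cube, w, windows = windows,
                    reference = roles[["reference"]], test = roles[["test"]])
    p <- bt$p[match(ids, bt$protein_id)]

    ok <- det_test & !det_ref
    if (criteria$require_band_significance) {
      ok <- ok & p < criteria$p_threshold
    }
    qualifying[, wname] <- ok

    safe <- gsub("[^A-Za-z0-9]+", "_", wname)
    out[[paste0("det_ref_", safe)]] <- det_ref
    out[[paste0("det_test_", safe)]] <- det_test
    out[[paste0("p_", safe)]] <- p
  }

  n_reps <- criteria$min_replicates_detected
  pass_reps <- out$reps_test >= n_reps &
    (!criteria$require_reference_detection | out$reps_ref >= n_reps)
  pep_known <- !is.na(out$peptide_count)
  pass_pep <- pep_known & out$peptide_count >= criteria$min_peptides
  pass_window <- unname(rowSums(qualifying) > 0)

  out$qualifying_windows <- unname(apply(qualifying, 1, function(q) {
    paste(colnames(qualifying)[q], collapse = ",")
  }))
  out$candidate <- pass_reps & pass_pep & pass_window

  reasons <- character(length(ids))
  add_reason <- function(reasons, fail, msg) {
    ifelse(fail, ifelse(nzchar(reasons), paste(reasons, msg, sep = "; "), msg),
           reasons)
  }
  reasons <- add_reason(reasons, !pass_reps,
                        sprintf("detected in fewer than %d replicates", n_reps))
  reasons <- add_reason(reasons, !pass_pep,
                        sprintf("fewer than %d peptides", criteria$min_peptides))
  reasons <- add_reason(reasons, !pass_window,
                        "no window with test-only detection (and significance, if required)")
  out$reasons <- reasons
  out
}

#' Rank candidates by migration similarity to reference factors
#'
#' Pearson correlation between the max-normalized test-strain migration
#' profiles of candidate proteins and of known reference assembly factors.
#' Zero-variance (flat) profiles have no defined correlation and yield `NA`.
#'
#' @param cube A normalized [intensity_cube()].
#' @param candidates,references Protein ids.
#' @param strain Strain whose profiles are compared (default: the test
#'   strain).
#' @inheritParams welch_lane_test
#' @return Numeric matrix of correlations, candidates x references, rows
#'   ordered by best similarity (ties broken by protein id).
#' @export
rank_by_similarity <- function(cube, candidates, references, strain = NULL,
                               reference = NULL, test = NULL) {
  stopifnot(inherits(cube, "intensity_cube"))
  if (is.null(strain)) {
    strain <- strain_roles(cube, reference, test)[["test"]]
  }
  mat <- average_profiles(cube, strain)
  missing_ids <- setdiff(c(candidates, references), rownames(mat))
  if (length(missing_ids) > 0) {
    stop("unknown protein(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  norm <- max_normalize(mat[unique(c(candidates, references)), , drop = FALSE])
  sim <- matrix(NA_real_, length(candidates), length(references),
                dimnames = list(candidates, references))
  for (i in seq_along(candidates)) {
    x <- norm[candidates[i], ]
    if (stats::sd(x) == 0) next
    for (j in seq_along(references)) {
      y <- norm[references[j], ]
      if (stats::sd(y) == 0) next
      sim[i, j] <- stats::cor(x, y)
    }
  }
  best <- apply(sim, 1, function(r) if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  sim[order(-best, rownames(sim)), , drop = FALSE]
}
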