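# Vectorized two-sample t machinery on row-matched matrices of per-replicate
# sums. Welch (default) or pooled variance. Degenerate rows where both groups
# have zero variance get the documented total-function policy: p = 1 when the
# means are equal, p = 0 otherwise, flagged in the output.
.welch_rows <- function(X, Y, var_equal = FALSE) {
  nx <- ncol(X); ny <- ncol(Y)
  stopifnot(nx >= 2, ny >= 2, nrow(X) == nrow(Y))
  mx <- unname(rowMeans(X)); my <- unname(rowMeans(Y))
  vx <- unname(apply(X, 1, stats::var)); vy <- unname(apply(Y, 1, stats::var))

  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(mx))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }

  degenerate <- se == 0
  t_stat <- ifelse(degenerate, ifelse(mx == my, 0, Inf * sign(my - mx)),
                   (my - mx) / se)
  p <- ifelse(degenerate, ifelse(mx == my, 1, 0),
              2 * stats::pt(-abs(t_stat), df))
  tibble::tibble(t = t_stat, df = ifelse(degenerate, NA_real_, df), p = p,
                 mean_ref = mx, mean_test = my, degenerate = degenerate)
}

.replicate_sums <- function(cube, slices = NULL) {
  d <- cube$data
  if (!is.null(slices)) d <- dplyr::filter(d, .data$slice %in% slices)
  sums <- dplyr::summarise(d, total = sum(.data$intensity),
                           .by = c("protein_id", "strain", "replicate"))
  # proteins entirely absent from a window still need explicit zero rows
  if (!is.null(slices)) {
    sums <- tidyr::complete(sums,
                            protein_id = cube_proteins(cube),
                            tidyr::nesting(!!!cube$samples),
                            fill = list(total = 0))
  }
  sums
}

.sums_matrix <- function(sums, strain_label, ids) {
  wide <- dplyr::filter(sums, .data$strain == strain_label) |>
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "replicate",
                       values_from = "total", values_fill = 0) |>
    dplyr::arrange(.data$protein_id)
  mat <- as.matrix(wide[match(ids, wide$protein_id), -1, drop = FALSE])
  mat[is.na(mat)] <- 0
  rownames(mat) <- ids
  mat
}

#' Per-protein Welch test on normalized lane sums
#'
#' For every protein, sums the normalized intensities of all slices per
#' replicate lane and tests the reference strain's replicate sums against
#' the test strain's with a two-sided unequal-variance (Welch) t test.
#'
#' @param cube A normalized [intensity_cube()].
#' @param proteins Optional subset of protein ids (default: all).
#' @param reference,test Strain role assignment (see [strain_roles()]).
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return Tibble with one row per protein: `protein_id`, `scope`
#'   (`"whole-lane"`), `t`, `df` (Welch–Satterthwaite), `p`, `mean_ref`,
#'   `mean_test`, `degenerate` (zero-variance policy applied).
#' @export
welch_lane_test <- function(cube, proteins = NULL, reference = NULL,
                            test = NULL, var_equal = FALSE) {
  stopifnot(inherits(cube, "intensity_cube"))
  roles <- strain_roles(cube, reference, test)
  ids <- if (is.null(proteins)) cube_proteins(cube) else proteins
  sums <- .replicate_sums(cube)
  res <- .welch_rows(.sums_matrix(sums, roles[["reference"]], ids),
                     .sums_matrix(sums, roles[["test"]], ids),
                     var_equal = var_equal)
  dplyr::bind_cols(tibble::tibble(protein_id = ids, scope = "whole-lane"), res)
}

#' Per-protein test of summed intensities within a band window
#'
#' The same two-sample test as [welch_lane_test()], applied to per-replicate
#' sums over the slices of one band window — the per-band significance test
#' used to mark differential bands on migration-profile plots.
#'
#' @inheritParams welch_lane_test
#' @param window A [band_window()] or the name of a window in `windows`.
#' @param windows Named list of known windows.
#' @return Tibble as in [welch_lane_test()], with `scope` = window name.
#' @export
band_test <- function(cube, window, windows = psii_band_windows(),
                      proteins = NULL, reference = NULL, test = NULL,
                      var_equal = FALSE) {
  stopifnot(inherits(cube, "intensity_cube"))
  roles <- strain_roles(cube, reference, test)
  w <- .resolve_window(window, windows, cube$n_slices)
  ids <- if (is.null(proteins)) cube_proteins(cube) else proteins
  sums <- .replicate_sums(cube, slices = w$lo:w$hi)
  res <- .welch_rows(.sums_matrix(sums, roles[["reference"]], ids),
                     .sums_matrix(sums, roles[["test"]], ids),
                     var_equal = var_equal)
  dplyr::bind_cols(tibble::tibble(protein_id = ids, scope = w$name), res)
}

#' Amplitude-adjusted Euclidean distance between migration profiles
#'
#' The Euclidean distance between the two strains' replicate-averaged
#' profiles of one protein, divided by the maximal average slice intensity
#' over both profiles to remove amplitude-introduced bias; the adjusted
#' distance is invariant under joint positive scaling of both profiles.
#' With `amplitude = "per_strain"` each strain's own maximum is used
#' instead, yielding two adjusted distances.
#'
#' @param profile_ref,profile_test [average_profile()] results or plain
#'   numeric vectors of equal length.
#' @param amplitude `"joint"` (one denominator, the default) or
#'   `"per_strain"`.
#' @return A `profile_distance`: list with `euclidean`, `amplitude`,
#'   `adjusted` (and `adjusted_ref`/`adjusted_test` for `"per_strain"`),
#'   `degenerate` (both profiles all-zero; adjusted set to 0).
#' @export
profile_distance <- function(profile_ref, profile_test,
                             amplitude = c("joint", "per_strain")) {
  amplitude <- match.arg(amplitude)
  x <- if (inherits(profile_ref, "migration_profile")) profile_ref$values else profile_ref
  y <- if (inherits(profile_test, "migration_profile")) profile_test$values else profile_test
  if (length(x) != length(y)) {
    stop("profiles differ in length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  euclid <- sqrt(sum((x - y)^2))
  amp <- max(x, y)
  degenerate <- amp == 0
  out <- list(euclidean = euclid, amplitude = amp,
              adjusted = if (degenerate) 0 else euclid / amp,
              degenerate = degenerate)
  if (amplitude == "per_strain") {
    out$adjusted_ref <- if (max(x) == 0) 0 else euclid / max(x)
    out$adjusted_test <- if (max(y) == 0) 0 else euclid / max(y)
  }
  structure(out, class = "profile_distance")
}

#' Profile distances for all proteins of a cube
#'
#' @param cube A normalized [intensity_cube()].
#' @inheritParams welch_lane_test
#' @return Tibble with `protein_id`, `euclidean`, `amplitude`, `adjusted`,
#'   `degenerate`.
#' @export
profile_distance_table <- function(cube, reference = NULL, test = NULL) {
  roles <- strain_roles(cube, reference, test)
  ref_mat <- average_profiles(cube, roles[["reference"]])
  test_mat <- average_profiles(cube, roles[["test"]])
  ids <- rownames(ref_mat)
  diffs <- ref_mat - test_mat[ids, , drop = FALSE]
  euclid <- sqrt(rowSums(diffs^2))
  amp <- pmax(apply(ref_mat, 1, max), apply(test_mat[ids, , drop = FALSE], 1, max))
  tibble::tibble(
    protein_id = ids, euclidean = euclid, amplitude = amp,
    adjusted = ifelse(amp == 0, 0, euclid / amp),
    degenerate = amp == 0
  )
}

#' Bonferroni–Holm adjustment
#'
#' Step-down Holm correction with monotonicity enforcement, capped at 1;
#' the adjustment used for the immunoblot-style multi-strain comparisons.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Normalize immunoblot signals across antisera and experiments
#'
#' Densitometric signals are made comparable in two steps: each signal is
#' divided by the median of all signals obtained with the same antiserum in
#' the same experiment (removing per-blot exposure and loading scale), and
#' then by the mean of the reference strain's step-one values for that
#' antiserum, so the reference strain maps to 1 on average.
#'
#' @param signals Data frame with columns `signal` (>= 0), `antiserum`,
#'   `experiment`, `strain`.
#' @param reference_strain Strain whose mean is mapped to 1.
#' @return The input tibble with columns `scaled` (after step one) and
#'   `normalized` (after both steps).
#' @export
blot_normalize <- function(signals, reference_strain) {
  signals <- tibble::as_tibble(signals)
  required <- c("signal", "antiserum", "experiment", "strain")
  missing_cols <- setdiff(required, names(signals))
  if (length(missing_cols) > 0) {
    stop("signals lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!reference_strain %in% signals$strain) {
    stop("reference strain ", reference_strain, " absent from signals",
         call. = FALSE)
  }
  out <- dplyr::mutate(signals,
                       .med = stats::median(.data$signal),
                       .by = c("antiserum", "experiment"))
  if (any(out$.med <= 0)) {
    stop("all-zero signal group for some (antiserum, experiment)",
         call. = FALSE)
  }
  out$scaled <- out$signal / out$.med
  out <- dplyr::mutate(
    out,
    .ref = mean(.data$scaled[.data$strain == reference_strain]),
    .by = "antiserum"
  )
  if (any(is.nan(out$.ref) | out$.ref <= 0)) {
    stop("reference strain has no usable signal for some antiserum",
         call. = FALSE)
  }
  out$normalized <- out$scaled / out$.ref
  dplyr::select(out, -".med", -".ref")
}

#' Per-cell molar abundance from a protein mass fraction
#'
#' Converts a protein's fraction of total cellular protein into a per-cell
#' molar amount: amount \[amol/cell\] = (fraction/100 x total protein
#' \[pg/cell\]) / molar mass \[kDa\] x 10. (1 pg / (1 kDa x 1000 g/mol) =
#' 1e-19 mol = 0.1 amol.) Optionally reports how many-fold a reference
#' species (e.g. the PSII complex) exceeds it.
#'
#' @param fraction_percent Mass fraction of total protein, in percent (> 0).
#' @param total_protein_pg Total protein per cell, picograms (> 0).
#' @param molar_mass_kda Molar mass of the protein, kilodaltons (> 0).
#' @param reference_amount_amol Optional reference amount, attomol/cell.
#' @return A `cell_stoichiometry`: list with the inputs, `amount_amol`, and
#'   `fold_vs_reference` (`NA` if no reference given).
#' @examples
#' abundance_per_cell(0.0034, 25, 12.5, reference_amount_amol = 5.2)
#' @export
abundance_per_cell <- function(fraction_percent, total_protein_pg,
                               molar_mass_kda, reference_amount_amol = NULL) {
  vals <- c(fraction_percent, total_protein_pg, molar_mass_kda,
            reference_amount_amol)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be positive and finite", call. = FALSE)
  }
  # pg -> g: 1e-12; / (kDa x 1000 g/mol) -> mol; mol -> amol: 1e18.
  # Net: amount = fraction/100 x pg / kDa x 1000.
  amount <- fraction_percent / 100 * total_protein_pg / molar_mass_kda * 1000
  fold <- if (is.null(reference_amount_amol)) NA_real_ else reference_amount_amol / amount
  structure(
    list(fraction_of_total_protein = fraction_percent,
         total_protein_per_cell = total_protein_pg,
         molar_mass = molar_mass_kda,
         amount_amol = amount, fold_vs_reference = fold),
    class = "cell_stoichiometry"
  )
}

#' @export
print.cell_stoichiometry <- function(x, ...) {
  cat(format(x$fraction_of_total_protein), "% of ",
      format(x$total_protein_per_cell), " pg total protein at ",
      format(x$molar_mass), " kDa -> ",
      format(round(x$amount_amol, 2)), " amol/cell", sep = "")
  if (!is.na(x$fold_vs_reference)) {
    cat(" (reference is ", format(round(x$fold_vs_reference, 1)),
        "-fold more abundant)", sep = "")
  }
  cat("\n")
  invisible(x)
}
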