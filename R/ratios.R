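#' Detection policy for band-window intensities
#'
#' A protein's summed intensity in a scope (whole lane or band window) counts
#' as "detected" in a strain iff it reaches `threshold_fraction` of that
#' strain's total intensity (all proteins, all replicates, all slices).
#' The not-detected rule is strict: strictly below the threshold is ND, so a
#' sum at exactly the threshold is detected. The default 0.0005 corresponds
#' to 0.05% of the strain total.
#'
#' @param threshold_fraction Fraction of the strain total, in \[0, 1).
#' @return A `detection_policy` object.
#' @export
detection_policy <- function(threshold_fraction = 0.0005) {
  if (!is.finite(threshold_fraction) || threshold_fraction < 0 ||
      threshold_fraction >= 1) {
    stop("threshold_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(list(threshold_fraction = threshold_fraction),
            class = "detection_policy")
}

#' Total intensity per strain
#'
#' Sum of all proteins' intensities over every replicate and slice of one
#' strain — the denominator of the detection rule.
#'
#' @param cube An [intensity_cube()].
#' @return Named numeric vector, one total per strain.
#' @export
strain_totals <- function(cube) {
  stopifnot(inherits(cube, "intensity_cube"))
  tot <- dplyr::summarise(cube$data, total = sum(.data$intensity),
                          .by = "strain")
  stats::setNames(tot$total, tot$strain)
}

#' Detection call for a summed intensity
#'
#' @param sum Summed intensity of a protein in a scope (>= 0).
#' @param strain_total The strain's total intensity (> 0).
#' @param policy A [detection_policy()].
#' @return Logical: detected?
#' @export
is_detected <- function(sum, strain_total, policy = detection_policy()) {
  stopifnot(inherits(policy, "detection_policy"))
  if (any(strain_total <= 0)) stop("strain total must be > 0", call. = FALSE)
  sum >= policy$threshold_fraction * strain_total
}

#' Summed intensities of one protein per strain
#'
#' Sums over all replicates and the slices of a band window (the whole lane
#' when no window is given), for the reference and the test strain.
#'
#' @param cube A normalized [intensity_cube()].
#' @param protein Protein id.
#' @param window Optional [band_window()] or window name.
#' @param windows Named list of known windows.
#' @inheritParams welch_lane_test
#' @return Named numeric vector `c(sum_ref, sum_test)`.
#' @export
window_sums <- function(cube, protein, window = NULL,
                        windows = psii_band_windows(),
                        reference = NULL, test = NULL) {
  stopifnot(inherits(cube, "intensity_cube"))
  roles <- strain_roles(cube, reference, test)
  d <- dplyr::filter(cube$data, .data$protein_id == protein)
  if (!is.null(window)) {
    w <- .resolve_window(window, windows, cube$n_slices)
    d <- dplyr::filter(d, .data$slice >= w$lo, .data$slice <= w$hi)
  }
  c(sum_ref = sum(d$intensity[d$strain == roles[["reference"]]]),
    sum_test = sum(d$intensity[d$strain == roles[["test"]]]))
}

#' Mutant/reference abundance ratio table with detection flags
#'
#' For every protein and scope (whole lane plus each band window), sums the
#' normalized intensities over replicates and the scope's slices in each
#' strain and reports the test/reference ratio. The ratio is defined only
#' when the protein is detected in both strains under the detection policy;
#' otherwise the record carries the conventional flag: `"ND"` (not detected
#' in the reference strain), `"nd"` (not detected in the test strain), or
#' `"nd/ND"` (neither).
#'
#' @param cube A normalized [intensity_cube()].
#' @param windows Named list of [band_window()]s (set `NULL` for whole-lane
#'   records only).
#' @param policy A [detection_policy()].
#' @inheritParams welch_lane_test
#' @return Tibble with columns `protein_id`, `scope`, `sum_ref`, `sum_test`,
#'   `detected_ref`, `detected_test`, `ratio` (NA when undefined), `flag`.
#' @export
ratio_table <- function(cube, windows = psii_band_windows(),
                        policy = detection_policy(),
                        reference = NULL, test = NULL) {
  stopifnot(inherits(cube, "intensity_cube"))
  roles <- strain_roles(cube, reference, test)
  totals <- strain_totals(cube)

  scopes <- c(list(`whole-lane` = NULL), windows)
  records <- lapply(names(scopes), function(scope_name) {
    w <- scopes[[scope_name]]
    slices <- if (is.null(w)) NULL else .resolve_window(w, windows, cube$n_slices)
    d <- cube$data
    if (!is.null(slices)) {
      d <- dplyr::filter(d, .data$slice >= slices$lo, .data$slice <= slices$hi)
    }
    sums <- dplyr::summarise(d, total = sum(.data$intensity),
                             .by = c("protein_id", "strain")) |>
      tidyr::complete(protein_id = cube_proteins(cube),
                      strain = cube$samples$strain |> unique(),
                      fill = list(total = 0)) |>
      tidyr::pivot_wider(names_from = "strain", values_from = "total")
    tibble::tibble(
      protein_id = sums$protein_id,
      scope = scope_name,
      sum_ref = sums[[roles[["reference"]]]],
      sum_test = sums[[roles[["test"]]]]
    )
  })
  out <- dplyr::bind_rows(records)
  out$detected_ref <- is_detected(out$sum_ref, totals[[roles[["reference"]]]],
                                  policy)
  out$detected_test <- is_detected(out$sum_test, totals[[roles[["test"]]]],
                                   policy)
  both <- out$detected_ref & out$detected_test
  out$ratio <- ifelse(both, out$sum_test / out$sum_ref, NA_real_)
  out$flag <- dplyr::case_when(
    both ~ "",
    !out$detected_ref & !out$detected_test ~ "nd/ND",
    !out$detected_ref ~ "ND",
    TRUE ~ "nd"
  )
  out
}

#' Complex-level median of member ratios
#'
#' Summarizes a complex by the median of its members' defined test/reference
#' ratios (midpoint of the central pair for even counts). Members without a
#' defined ratio, and explicitly excluded members (e.g. non-canonical
#' subunits whose abundance is not co-regulated with the complex), are
#' listed with the reason for their exclusion.
#'
#' @param ratios Either a [ratio_table()] result (rows with a single scope)
#'   or any data frame with columns `protein_id` and `ratio`, or a named
#'   numeric vector of ratios.
#' @param members Character vector of member protein ids.
#' @param name Complex label for the summary.
#' @param exclude Members to leave out of the median.
#' @param round_digits Optionally round each member ratio before taking the
#'   median, to reproduce tables typeset at fixed precision.
#' @return A `complex_summary`: list with `complex`, `median_ratio`,
#'   `members_used`, `ratios_used`, `excluded` (named character of reasons).
#' @export
complex_median_ratio <- function(ratios, members, name = "complex",
                                 exclude = NULL, round_digits = NULL) {
  if (is.numeric(ratios) && !is.null(names(ratios))) {
    ratios <- tibble::tibble(protein_id = names(ratios), ratio = unname(ratios))
  }
  ratios <- tibble::as_tibble(ratios)
  stopifnot(all(c("protein_id", "ratio") %in% names(ratios)))
  if (anyDuplicated(ratios$protein_id)) {
    stop("one ratio per protein required; filter to a single scope first",
         call. = FALSE)
  }

  excluded <- character(0)
  for (m in intersect(exclude, members)) excluded[m] <- "excluded by request"
  use <- setdiff(members, exclude)
  miss <- setdiff(use, ratios$protein_id)
  for (m in miss) excluded[m] <- "no ratio record"
  use <- intersect(use, ratios$protein_id)

  vals <- ratios$ratio[match(use, ratios$protein_id)]
  undef <- is.na(vals)
  for (m in use[undef]) excluded[m] <- "ratio undefined (not detected)"
  use <- use[!undef]
  vals <- vals[!undef]
  if (length(vals) == 0) {
    stop("no member of ", name, " has a defined ratio", call. = FALSE)
  }
  if (!is.null(round_digits)) vals <- round(vals, round_digits)

  structure(
    list(complex = name, median_ratio = stats::median(vals),
         members_used = use, ratios_used = stats::setNames(vals, use),
         excluded = excluded),
    class = "complex_summary"
  )
}

#' @export
print.complex_summary <- function(x, ...) {
  cat("<complex_summary> ", x$complex, ": median ratio ",
      format(x$median_ratio), " over ", length(x$members_used),
      " member(s)", sep = "")
  if (length(x$excluded) > 0) {
    cat("; excluded: ", paste(names(x$excluded), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}
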