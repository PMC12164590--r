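#' Per-protein lane totals (total ion intensity sums)
#'
#' Sums each protein's intensity over all slices of each sample's lane: the
#' total ion intensity sum (TIS) underlying both normalization and the
#' lane-level Welch tests.
#'
#' @param cube An [intensity_cube()].
#' @return Tibble with columns `protein_id`, `strain`, `replicate`, `total`.
#' @export
lane_totals <- function(cube) {
  stopifnot(inherits(cube, "intensity_cube"))
  dplyr::summarise(cube$data, total = sum(.data$intensity),
                   .by = c("protein_id", "strain", "replicate"))
}

#' Anchor-set median-of-ratios size factors
#'
#' Computes one multiplicative correction factor per sample from the lane
#' totals of a set of anchor proteins assumed equally abundant across
#' conditions (canonically the eight ATP synthase subunits). For each anchor
#' the reference value is the geometric mean of its lane totals across all
#' samples; the sample's factor is the median over anchors of
#' total(anchor, sample) / reference(anchor) — the median-of-ratios
#' estimator. Anchors with a zero lane total in any sample are excluded (and
#' reported), since they break the geometric mean.
#'
#' @param cube An [intensity_cube()].
#' @param anchors Character vector of anchor protein ids.
#' @return A `cp_normalization` object: list with `factors` (tibble `strain`,
#'   `replicate`, `tis`, `size_factor`), `reference` (named per-anchor
#'   geometric means), `anchors_used`, `anchors_dropped`.
#' @export
size_factors <- function(cube, anchors) {
  stopifnot(inherits(cube, "intensity_cube"), length(anchors) >= 1)
  missing_anchors <- setdiff(anchors, cube_proteins(cube))
  if (length(missing_anchors) > 0) {
    message("anchor(s) not in cube: ", paste(missing_anchors, collapse = ", "))
  }
  anchors <- intersect(anchors, cube_proteins(cube))

  totals <- lane_totals(cube)
  tis <- dplyr::summarise(totals, tis = sum(.data$total),
                          .by = c("strain", "replicate"))

  at <- dplyr::filter(totals, .data$protein_id %in% anchors) |>
    tidyr::pivot_wider(names_from = c("strain", "replicate"),
                       values_from = "total")
  mat <- as.matrix(at[, -1, drop = FALSE])
  rownames(mat) <- at$protein_id

  usable <- rowSums(mat <= 0) == 0
  dropped <- rownames(mat)[!usable]
  if (length(dropped) > 0) {
    message("anchor(s) with zero lane totals dropped: ",
            paste(dropped, collapse = ", "))
  }
  mat <- mat[usable, , drop = FALSE]
  if (nrow(mat) == 0) {
    stop("no usable anchors: every anchor has a zero lane total in some sample",
         call. = FALSE)
  }

  reference <- exp(rowMeans(log(mat)))
  ratios <- mat / reference
  factors <- apply(ratios, 2, stats::median)

  samples <- dplyr::arrange(cube$samples, .data$strain, .data$replicate)
  key <- paste(samples$strain, samples$replicate, sep = "_")
  out <- dplyr::left_join(samples, tis, by = c("strain", "replicate"))
  out$size_factor <- unname(factors[key])

  structure(
    list(factors = out, reference = reference,
         anchors_used = rownames(mat), anchors_dropped = dropped),
    class = "cp_normalization"
  )
}

#' @export
print.cp_normalization <- function(x, ...) {
  cat("<cp_normalization> ", length(x$anchors_used), " anchors\n", sep = "")
  print(x$factors)
  invisible(x)
}

#' Apply size factors to a cube
#'
#' Divides every intensity value by its sample's correction factor, so the
#' anchor lane totals (and, to the extent loading is the only difference,
#' all totals) are equalized across samples.
#'
#' @param cube An [intensity_cube()].
#' @param normalization A [size_factors()] result.
#' @return The normalized [intensity_cube()].
#' @export
apply_size_factors <- function(cube, normalization) {
  stopifnot(inherits(cube, "intensity_cube"),
            inherits(normalization, "cp_normalization"))
  f <- normalization$factors
  if (any(!is.finite(f$size_factor)) || any(f$size_factor <= 0)) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  covered <- dplyr::anti_join(cube$samples,
                              f[, c("strain", "replicate")],
                              by = c("strain", "replicate"))
  if (nrow(covered) > 0) {
    stop("size factors missing for ", nrow(covered), " sample(s)", call. = FALSE)
  }
  .divide_by_sample_factor(cube, f[, c("strain", "replicate", "size_factor")])
}

#' Normalize a cube with anchor proteins in one step
#'
#' Convenience wrapper: [size_factors()] followed by [apply_size_factors()].
#'
#' @inheritParams size_factors
#' @return The normalized cube, with the `cp_normalization` attached as
#'   attribute `"normalization"`.
#' @export
normalize_cube <- function(cube, anchors) {
  res <- size_factors(cube, anchors)
  out <- apply_size_factors(cube, res)
  attr(out, "normalization") <- res
  out
}
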