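#' Intensity cube: slice-resolved protein intensities
#'
#' The central data structure of the package: per-protein, per-strain,
#' per-replicate, per-slice non-negative intensities from a BN-PAGE x LC-MS/MS
#' experiment, together with per-protein metadata (gene label, peptide count,
#' proteotypic flag, complex/category annotation).
#'
#' The cube is dense: every combination of protein, sample (strain x
#' replicate) and slice 1..N carries a value; non-detection is stored as 0,
#' which is how all downstream sums and detection thresholds treat it.
#'
#' @param data A data frame with columns `protein_id`, `strain`, `replicate`,
#'   `slice`, `intensity`. Missing (protein, sample, slice) cells are filled
#'   with 0. Intensities must be non-negative and finite.
#' @param proteins Optional per-protein metadata with column `protein_id` and
#'   any of `gene`, `peptide_count`, `proteotypic`, `complex`, `category`.
#'   Proteins present in `data` but not here get default metadata.
#' @param n_slices Number of gel slices per lane. Defaults to the largest
#'   slice index seen in `data`.
#'
#' @return An object of class `intensity_cube`: a list with elements
#'   `data` (long tibble, dense), `proteins` (metadata tibble), `samples`
#'   (tibble of strain/replicate pairs) and `n_slices`.
#' @examples
#' df <- expand.grid(protein_id = "P1", strain = c("WT", "mut"),
#'                   replicate = 1:2, slice = 1:4)
#' df$intensity <- 1
#' cube <- intensity_cube(df)
#' cube
#' @export
intensity_cube <- function(data, proteins = NULL, n_slices = NULL) {
  data <- tibble::as_tibble(data)
  required <- c("protein_id", "strain", "replicate", "slice", "intensity")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("intensity data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- dplyr::mutate(
    data,
    protein_id = as.character(.data$protein_id),
    strain = as.character(.data$strain),
    replicate = as.integer(.data$replicate),
    slice = as.integer(.data$slice),
    intensity = as.double(.data$intensity)
  )
  if (any(!is.finite(data$intensity)) || any(data$intensity < 0)) {
    bad <- which(!is.finite(data$intensity) | data$intensity < 0)[1]
    stop("negative or non-finite intensity at row ", bad, call. = FALSE)
  }
  if (is.null(n_slices)) n_slices <- max(data$slice, 1L)
  if (any(data$slice < 1L | data$slice > n_slices)) {
    stop("slice indices must lie in 1..", n_slices, call. = FALSE)
  }
  dup <- duplicated(data[, c("protein_id", "strain", "replicate", "slice")])
  if (any(dup)) {
    stop("duplicate (protein, strain, replicate, slice) row at input row ",
         which(dup)[1], call. = FALSE)
  }

  samples <- dplyr::distinct(data, .data$strain, .data$replicate) |>
    dplyr::arrange(.data$strain, .data$replicate)
  ids <- sort(unique(data$protein_id))

  # densify: absent cells are zero intensity
  grid <- tidyr::expand_grid(
    protein_id = ids,
    samples,
    slice = seq_len(n_slices)
  )
  dense <- dplyr::left_join(
    grid, data,
    by = c("protein_id", "strain", "replicate", "slice")
  )
  dense$intensity[is.na(dense$intensity)] <- 0

  proteins <- .complete_protein_meta(proteins, ids)

  structure(
    list(data = dense, proteins = proteins, samples = samples,
         n_slices = as.integer(n_slices)),
    class = "intensity_cube"
  )
}

.complete_protein_meta <- function(proteins, ids) {
  defaults <- tibble::tibble(
    protein_id = ids,
    gene = ids,
    peptide_count = NA_integer_,
    proteotypic = NA,
    complex = NA_character_,
    category = NA_character_
  )
  if (is.null(proteins)) return(defaults)
  proteins <- tibble::as_tibble(proteins)
  if (!"protein_id" %in% names(proteins)) {
    stop("protein metadata needs a protein_id column", call. = FALSE)
  }
  proteins$protein_id <- as.character(proteins$protein_id)
  unmatched <- setdiff(proteins$protein_id, ids)
  if (length(unmatched) > 0) {
    message("protein metadata for ", length(unmatched),
            " id(s) not present in the cube was ignored")
  }
  keep <- intersect(names(defaults), names(proteins))
  merged <- dplyr::left_join(defaults[, "protein_id", drop = FALSE],
                             proteins[, keep, drop = FALSE],
                             by = "protein_id")
  for (col in setdiff(names(defaults), names(merged))) {
    merged[[col]] <- defaults[[col]]
  }
  if (!is.null(merged$peptide_count)) {
    merged$peptide_count <- as.integer(merged$peptide_count)
  }
  merged$gene[is.na(merged$gene)] <- merged$protein_id[is.na(merged$gene)]
  merged[, names(defaults)]
}

#' @export
print.intensity_cube <- function(x, ...) {
  cat("<intensity_cube> ", nrow(x$proteins), " proteins, ",
      nrow(x$samples), " samples (",
      paste(unique(x$samples$strain), collapse = ", "), "), ",
      x$n_slices, " slices\n", sep = "")
  invisible(x)
}

#' Protein identifiers of a cube
#' @param cube An [intensity_cube()].
#' @return Character vector of protein ids.
#' @export
cube_proteins <- function(cube) cube$proteins$protein_id

#' Sample table of a cube
#' @param cube An [intensity_cube()].
#' @return Tibble with one row per (strain, replicate) sample.
#' @export
cube_samples <- function(cube) cube$samples

#' Assign reference/test roles to the two strains of an analysis
#'
#' Two-condition operations (ratio tables, Welch tests, the comigration
#' screen) need to know which strain is the reference (wild type) and which
#' is the test strain (mutant). Roles may be given explicitly; by default a
#' strain named `"WT"` is the reference, otherwise the alphabetically first
#' strain.
#'
#' @param cube An [intensity_cube()] with at least two strains.
#' @param reference,test Strain labels; `NULL` for the default assignment.
#' @return Named character vector with elements `reference` and `test`.
#' @export
strain_roles <- function(cube, reference = NULL, test = NULL) {
  strains <- unique(cube$samples$strain)
  if (length(strains) < 2 && (is.null(reference) || is.null(test))) {
    stop("strain role assignment needs two strains", call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- if ("WT" %in% strains) "WT" else sort(strains)[1]
  }
  if (is.null(test)) test <- setdiff(strains, reference)[1]
  if (!all(c(reference, test) %in% strains)) {
    stop("strain(s) not present in cube: ",
         paste(setdiff(c(reference, test), strains), collapse = ", "),
         call. = FALSE)
  }
  if (reference == test) stop("reference and test strain must differ", call. = FALSE)
  c(reference = reference, test = test)
}

#' Keep only proteins identified by proteotypic peptides
#'
#' Proteins identified exclusively by peptides shared between protein groups
#' cannot be quantified unambiguously and are discarded before any statistics.
#' If the cube carries no proteotypic flags the cube is returned unchanged
#' with a warning, so that pipelines on minimal inputs keep running.
#'
#' @param cube An [intensity_cube()] whose metadata carries a `proteotypic`
#'   logical column.
#' @return A filtered [intensity_cube()].
#' @export
filter_proteotypic <- function(cube) {
  stopifnot(inherits(cube, "intensity_cube"))
  flags <- cube$proteins$proteotypic
  if (all(is.na(flags))) {
    warning("no proteotypic flags present; returning cube unchanged")
    return(cube)
  }
  keep <- cube$proteins$protein_id[!is.na(flags) & flags]
  dropped <- setdiff(cube$proteins$protein_id, keep)
  if (length(dropped) > 0) {
    message("discarding ", length(dropped),
            " protein(s) without proteotypic evidence")
  }
  subset_cube(cube, keep)
}

#' Subset a cube to a set of proteins
#' @param cube An [intensity_cube()].
#' @param protein_ids Character vector of ids to keep (may be empty).
#' @return An [intensity_cube()] restricted to `protein_ids`.
#' @export
subset_cube <- function(cube, protein_ids) {
  stopifnot(inherits(cube, "intensity_cube"))
  cube$data <- dplyr::filter(cube$data, .data$protein_id %in% protein_ids)
  cube$proteins <- dplyr::filter(cube$proteins, .data$protein_id %in% protein_ids)
  cube
}

#' Scale every intensity of selected samples
#'
#' Internal workhorse for normalization: divides each value by a per-sample
#' factor.
#' @noRd
.divide_by_sample_factor <- function(cube, factors) {
  # factors: tibble(strain, replicate, size_factor)
  cube$data <- dplyr::left_join(cube$data, factors,
                                by = c("strain", "replicate")) |>
    dplyr::mutate(intensity = .data$intensity / .data$size_factor) |>
    dplyr::select(-"size_factor")
  cube
}
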