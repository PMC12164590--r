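#' Read a long-format slice intensity table
#'
#' The long TSV dialect has one row per (protein, strain, replicate, slice)
#' cell with columns `protein_id`, `strain`, `replicate`, `slice`,
#' `intensity`, and optionally `peptide_count`, `proteotypic`, `gene`,
#' `complex`, `category`. Cells absent from the file are filled with zero
#' intensity; negative intensities and duplicate cells are errors that name
#' the offending row.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return An [intensity_cube()].
#' @export
read_long_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  required <- c("protein_id", "strain", "replicate", "slice", "intensity")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0) {
    stop(path, " contains no data rows", call. = FALSE)
  }
  meta_cols <- intersect(
    c("protein_id", "gene", "peptide_count", "proteotypic", "complex",
      "category"),
    names(tab)
  )
  proteins <- NULL
  if (length(meta_cols) > 1) {
    proteins <- dplyr::distinct(tab[, meta_cols])
    if (anyDuplicated(proteins$protein_id)) {
      stop("inconsistent protein metadata for id ",
           proteins$protein_id[duplicated(proteins$protein_id)][1],
           call. = FALSE)
    }
  }
  intensity_cube(tab[, required], proteins = proteins)
}

#' Write a cube in the long TSV dialect
#'
#' Inverse of [read_long_tsv()]: emits one row per cell (zeros included, so
#' a write/read round trip is exact) with the protein metadata columns joined
#' in. Values are written at full double precision.
#'
#' @param cube An [intensity_cube()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_tsv <- function(cube, path) {
  stopifnot(inherits(cube, "intensity_cube"))
  out <- dplyr::left_join(cube$data, cube$proteins, by = "protein_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a wide (one column per sample x slice) intensity table
#'
#' Search-engine exports commonly carry one row per protein group and one
#' intensity column per sample and slice. Column names are parsed with a
#' regular expression whose first three capture groups are (strain,
#' replicate, slice); the default matches names like
#' `"Intensity WT_2_slice17"`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param sample_pattern Regular expression with three capture groups
#'   (strain, replicate, slice) applied to every non-metadata column.
#' @return An [intensity_cube()] identical to the one the long reader builds
#'   from the same data.
#' @export
read_wide_slices <- function(path,
                             sample_pattern = "^Intensity ([^_]+)_([0-9]+)_slice([0-9]+)$") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  if (!"protein_id" %in% names(tab)) {
    stop(path, " lacks a protein_id column", call. = FALSE)
  }
  meta_cols <- intersect(
    c("protein_id", "gene", "peptide_count", "proteotypic", "complex",
      "category"),
    names(tab)
  )
  value_cols <- setdiff(names(tab), meta_cols)
  if (length(value_cols) == 0) stop(path, " has no intensity columns", call. = FALSE)
  ok <- grepl(sample_pattern, value_cols)
  if (any(!ok)) {
    stop("column name(s) not matching the sample pattern: ",
         paste(value_cols[!ok], collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(tab, cols = dplyr::all_of(value_cols),
                              names_to = "sample", values_to = "intensity")
  m <- regmatches(long$sample, regexec(sample_pattern, long$sample))
  long$strain <- vapply(m, `[`, "", 2)
  long$replicate <- as.integer(vapply(m, `[`, "", 3))
  long$slice <- as.integer(vapply(m, `[`, "", 4))
  proteins <- if (length(meta_cols) > 1) dplyr::distinct(tab[, meta_cols]) else NULL
  intensity_cube(
    long[, c("protein_id", "strain", "replicate", "slice", "intensity")],
    proteins = proteins
  )
}

#' Read an annotation table and attach it to a cube
#'
#' The annotation TSV maps protein ids to complex membership and subunit
#' class (columns `protein_id`, `complex`, `category`, optional `gene`).
#' Ids that do not resolve against the cube are reported but not fatal.
#'
#' @param cube An [intensity_cube()].
#' @param path Path to the annotation TSV.
#' @return The cube with updated protein metadata.
#' @export
annotate_cube <- function(cube, path) {
  stopifnot(inherits(cube, "intensity_cube"))
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"protein_id" %in% names(ann)) {
    stop(path, " lacks a protein_id column", call. = FALSE)
  }
  ann$protein_id <- as.character(ann$protein_id)
  keep <- intersect(c("protein_id", "gene", "complex", "category"), names(ann))
  merged <- dplyr::rows_update(
    cube$proteins,
    dplyr::filter(ann[, keep], .data$protein_id %in% cube$proteins$protein_id),
    by = "protein_id"
  )
  unmatched <- setdiff(ann$protein_id, cube$proteins$protein_id)
  if (length(unmatched) > 0) {
    message(length(unmatched), " annotation id(s) not present in the cube")
  }
  cube$proteins <- merged
  cube
}

#' Define a named band window
#'
#' A band window is an inclusive 1-based slice range of a BN-PAGE lane, e.g.
#' the region where PSII reaction-center intermediates (RCII) migrate.
#'
#' @param name Window label.
#' @param lo,hi First and last slice of the window (inclusive, `lo <= hi`).
#' @return A `band_window` object.
#' @export
band_window <- function(name, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (is.na(lo) || is.na(hi) || lo < 1L || lo > hi) {
    stop("band window needs 1 <= lo <= hi", call. = FALSE)
  }
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "band_window")
}

#' @export
print.band_window <- function(x, ...) {
  cat("<band_window> ", x$name, ": slices ", x$lo, "-", x$hi, "\n", sep = "")
  invisible(x)
}

#' Default PSII assembly-state band windows
#'
#' The band windows of the 36-slice BN-PAGE layout used throughout the
#' package: supercomplexes (SC) 7-11, dimers 13-15, monomers/RC47 17-18,
#' RCII 22-23, the CP43 module 25-26, and the D1 module / unassembled
#' PsbE/F region 28-30.
#'
#' @return Named list of [band_window()] objects.
#' @export
psii_band_windows <- function() {
  windows <- list(
    band_window("SC", 7, 11),
    band_window("Dimers", 13, 15),
    band_window("Monomers/RC47", 17, 18),
    band_window("RCII", 22, 23),
    band_window("CP43_mod", 25, 26),
    band_window("D1_mod/PsbE/F", 28, 30)
  )
  stats::setNames(windows, vapply(windows, `[[`, "", "name"))
}

.resolve_window <- function(window, windows = psii_band_windows(), n_slices) {
  if (inherits(window, "band_window")) {
    w <- window
  } else if (is.character(window) && length(window) == 1) {
    if (!window %in% names(windows)) {
      stop("unknown band window: ", window, call. = FALSE)
    }
    w <- windows[[window]]
  } else {
    stop("window must be a band_window or a window name", call. = FALSE)
  }
  if (w$hi > n_slices) {
    stop("band window ", w$name, " exceeds the lane (", n_slices, " slices)",
         call. = FALSE)
  }
  w
}
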