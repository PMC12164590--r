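#' Replicate-averaged migration profile of one protein
#'
#' The per-slice arithmetic mean over a strain's replicates: the migration
#' profile used for heat maps, profile distances and similarity ranking.
#'
#' @param cube An [intensity_cube()] (normalized, for any downstream use).
#' @param protein Protein id.
#' @param strain Strain label.
#' @return A `migration_profile`: list with `protein_id`, `strain`, `values`
#'   (length-N numeric), `n_replicates`.
#' @export
average_profile <- function(cube, protein, strain) {
  stopifnot(inherits(cube, "intensity_cube"))
  if (!protein %in% cube_proteins(cube)) {
    stop("unknown protein: ", protein, call. = FALSE)
  }
  if (!strain %in% cube$samples$strain) {
    stop("unknown strain: ", strain, call. = FALSE)
  }
  rows <- dplyr::filter(cube$data, .data$protein_id == protein,
                        .data$strain == !!strain)
  prof <- dplyr::summarise(rows, value = mean(.data$intensity),
                           .by = "slice") |>
    dplyr::arrange(.data$slice)
  structure(
    list(protein_id = protein, strain = strain, values = prof$value,
         n_replicates = length(unique(rows$replicate))),
    class = "migration_profile"
  )
}

#' Replicate-averaged profiles of all proteins of one strain
#'
#' Matrix form of [average_profile()]: one row per protein (sorted by id),
#' one column per slice.
#'
#' @param cube An [intensity_cube()].
#' @param strain Strain label.
#' @return Numeric matrix, rownames = protein ids.
#' @export
average_profiles <- function(cube, strain) {
  stopifnot(inherits(cube, "intensity_cube"))
  if (!strain %in% cube$samples$strain) {
    stop("unknown strain: ", strain, call. = FALSE)
  }
  means <- dplyr::filter(cube$data, .data$strain == !!strain) |>
    dplyr::summarise(value = mean(.data$intensity),
                     .by = c("protein_id", "slice"))
  wide <- tidyr::pivot_wider(means, names_from = "slice",
                             values_from = "value") |>
    dplyr::arrange(.data$protein_id)
  mat <- as.matrix(wide[, as.character(seq_len(cube$n_slices)), drop = FALSE])
  rownames(mat) <- wide$protein_id
  colnames(mat) <- seq_len(cube$n_slices)
  mat
}

#' Max-normalize migration profiles
#'
#' Divides each profile by its maximum slice value, so the slice with the
#' highest intensity maps to 1 — the scaling used for heat-map rows. All-zero
#' profiles stay all-zero; the operation is idempotent.
#'
#' @param x A `migration_profile`, a numeric vector, or a matrix (rows =
#'   proteins).
#' @return Object of the same shape with values in \[0, 1\].
#' @export
max_normalize <- function(x) {
  if (inherits(x, "migration_profile")) {
    x$values <- max_normalize(x$values)
    return(x)
  }
  if (is.matrix(x)) {
    m <- apply(x, 1, max)
    m[m == 0] <- 1
    return(x / m)
  }
  m <- max(x)
  if (m == 0) x else x / m
}

#' Cluster heat-map rows by migration behavior
#'
#' Agglomerative hierarchical clustering of (max-normalized) migration
#' profiles. Rows are first sorted by protein id so the result depends only
#' on the data, not on input order; proteins with identical profiles merge
#' at height 0 and end up adjacent.
#'
#' @param mat Numeric matrix, rows = proteins (rownames required).
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param k Optional number of clusters for [stats::cutree()] labels.
#' @return List with `order` (protein ids in dendrogram order), `labels`
#'   (named cluster labels, `NULL` unless `k` given) and `hclust` (the tree,
#'   `NULL` for a single row).
#' @export
cluster_rows <- function(mat, metric = "euclidean", linkage = "average",
                         k = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (nrow(mat) < 2) {
    labels <- if (!is.null(k)) stats::setNames(rep(1L, nrow(mat)), rownames(mat))
    return(list(order = rownames(mat), labels = labels, hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(mat, method = metric), method = linkage)
  labels <- if (!is.null(k)) stats::cutree(hc, k = k)
  list(order = rownames(mat)[hc$order], labels = labels, hclust = hc)
}

#' Heat-map matrix of one strain's migration profiles
#'
#' Builds the per-strain heat map: replicate-averaged profiles,
#' max-normalized per row, rows ordered either by hierarchical clustering of
#' migration behavior or by a given protein order.
#'
#' @param cube An [intensity_cube()].
#' @param strain Strain label.
#' @param proteins Optional protein ids (row subset and, if `cluster =
#'   FALSE`, row order).
#' @param cluster Cluster rows by migration behavior?
#' @param ... Passed to [cluster_rows()].
#' @return A numeric matrix with values in \[0, 1\], rows in display order;
#'   the clustering (if any) is attached as attribute `"clustering"`.
#' @export
heatmap_matrix <- function(cube, strain, proteins = NULL, cluster = TRUE, ...) {
  mat <- average_profiles(cube, strain)
  if (!is.null(proteins)) {
    missing_ids <- setdiff(proteins, rownames(mat))
    if (length(missing_ids) > 0) {
      stop("unknown protein(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    mat <- mat[proteins, , drop = FALSE]
  }
  mat <- max_normalize(mat)
  if (cluster && nrow(mat) >= 2) {
    cl <- cluster_rows(mat, ...)
    mat <- mat[cl$order, , drop = FALSE]
    attr(mat, "clustering") <- cl
  }
  mat
}

#' Write a heat-map matrix as TSV
#'
#' @param mat A [heatmap_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(mat, path) {
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  names(out) <- paste0("slice_", seq_len(ncol(mat)))
  out <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(mat)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Plot migration profiles of selected proteins
#'
#' Simple replicate-mean profile plot (one facet per protein, one line per
#' strain); requires ggplot2.
#'
#' @param cube An [intensity_cube()].
#' @param proteins Protein ids to plot.
#' @return A ggplot object.
#' @export
plot_profiles <- function(cube, proteins) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_profiles needs the ggplot2 package", call. = FALSE)
  }
  df <- dplyr::filter(cube$data, .data$protein_id %in% proteins) |>
    dplyr::summarise(value = mean(.data$intensity),
                     .by = c("protein_id", "strain", "slice"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$value,
                                   colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~protein_id, scales = "free_y") +
    ggplot2::labs(x = "gel slice", y = "mean normalized intensity")
}
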