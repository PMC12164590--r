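#' Build and validate a pipeline run configuration
#'
#' Collects everything a full analysis run needs: the input table, the strain
#' role assignment, the anchor set, band windows, detection policy, screen
#' criteria and clustering options. Unknown fields are rejected so that a
#' typo in a config file fails before any computation.
#'
#' @param input Path to a long-format intensity TSV (see [read_long_tsv()]).
#' @param out_dir Output directory for the report bundle.
#' @param reference,test Strain role assignment (`NULL`: defaults of
#'   [strain_roles()]).
#' @param anchors Anchor protein ids for normalization (default: the eight
#'   ATP synthase subunits of the demonstration complexome).
#' @param windows Named list, window name -> `c(lo, hi)` slice range
#'   (default: [psii_band_windows()]).
#' @param threshold_fraction Detection threshold as a fraction of the strain
#'   total.
#' @param screen Named list overriding [screen_criteria()] arguments
#'   (`windows`, `min_replicates_detected`, `min_peptides`,
#'   `require_band_significance`, `p_threshold`,
#'   `require_reference_detection`).
#' @param clustering Named list with `metric` and `linkage` for
#'   [cluster_rows()].
#' @param reference_factors Optional ids of known assembly factors for
#'   similarity ranking of screen candidates.
#' @param seed Integer seed (recorded in the log; the analysis itself is
#'   deterministic).
#' @return A validated `run_config` object.
#' @export
run_config <- function(input, out_dir,
                       reference = NULL, test = NULL,
                       anchors = c("AtpA", "AtpB", "ATPC", "ATPD", "AtpE",
                                   "AtpF", "ATPG", "atpI"),
                       windows = NULL, threshold_fraction = 0.0005,
                       screen = list(), clustering = list(),
                       reference_factors = NULL, seed = 1) {
  known_screen <- c("windows", "min_replicates_detected", "min_peptides",
                    "require_band_significance", "p_threshold",
                    "require_reference_detection")
  bad <- setdiff(names(screen), known_screen)
  if (length(bad) > 0) {
    stop("unknown screen option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  known_clust <- c("metric", "linkage")
  bad <- setdiff(names(clustering), known_clust)
  if (length(bad) > 0) {
    stop("unknown clustering option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  win_list <- if (is.null(windows)) {
    psii_band_windows()
  } else {
    ws <- lapply(names(windows), function(nm) {
      band_window(nm, windows[[nm]][1], windows[[nm]][2])
    })
    stats::setNames(ws, names(windows))
  }
  policy <- detection_policy(threshold_fraction)
  screen$policy <- policy
  if (is.null(screen$windows)) {
    screen$windows <- intersect(c("Monomers/RC47", "RCII"), names(win_list))
  }
  bad <- setdiff(screen$windows, names(win_list))
  if (length(bad) > 0) {
    stop("screened window(s) not defined: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(input = input, out_dir = out_dir, reference = reference, test = test,
         anchors = anchors, windows = win_list, policy = policy,
         screen = do.call(screen_criteria, screen),
         clustering = utils::modifyList(list(metric = "euclidean",
                                             linkage = "average"), clustering),
         reference_factors = reference_factors,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any argument of [run_config()]; unknown keys are
#' rejected. Relative paths are resolved against the file's directory.
#'
#' @param path Path to a YAML configuration file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("input", "out_dir")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(dirname(path), cfg[[key]])
    }
  }
  do.call(run_config, cfg)
}

#' Run the full complexome-profiling analysis
#'
#' Executes the analysis stages in order — read, proteotypic filter,
#' anchor-set normalization, per-strain heat maps with clustering, lane-level
#' Welch tests and profile distances, ratio tables with complex summaries,
#' and the comigration candidate screen — and writes a deterministic TSV
#' report bundle plus a log to the configured output directory.
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return Invisibly, a list with all computed artifacts (`cube`,
#'   `normalization`, `heatmaps`, `tests`, `distances`, `ratios`,
#'   `complex_summaries`, `candidates`, `similarity`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(
    paste0("comigrate ", as.character(utils::packageVersion("comigrate"))),
    paste0("input: ", config$input),
    paste0("seed: ", config$seed),
    paste0("anchors: ", paste(config$anchors, collapse = ", ")),
    paste0("windows: ",
           paste(vapply(config$windows, function(w) {
             paste0(w$name, "=", w$lo, "-", w$hi)
           }, ""), collapse = "; ")),
    paste0("detection threshold fraction: ",
           config$policy$threshold_fraction)
  )

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cube <- stage("read", read_long_tsv(config$input))
  cube <- stage("filter", suppressWarnings(filter_proteotypic(cube)))
  roles <- strain_roles(cube, config$reference, config$test)
  log_lines <- c(log_lines,
                 paste0("reference strain: ", roles[["reference"]]),
                 paste0("test strain: ", roles[["test"]]))

  normalization <- stage("normalize", size_factors(cube, config$anchors))
  cube <- stage("normalize", apply_size_factors(cube, normalization))
  readr::write_tsv(normalization$factors,
                   file.path(config$out_dir, "normalization.tsv"),
                   progress = FALSE)

  heatmaps <- list()
  for (s in unique(cube$samples$strain)) {
    hm <- stage("profiles",
                heatmap_matrix(cube, s, cluster = TRUE,
                               metric = config$clustering$metric,
                               linkage = config$clustering$linkage))
    safe <- gsub("[^A-Za-z0-9]+", "_", s)
    write_heatmap_tsv(hm, file.path(config$out_dir,
                                    paste0("heatmap_", safe, ".tsv")))
    heatmaps[[s]] <- hm
  }

  tests <- stage("stats", welch_lane_test(cube, reference = roles[["reference"]],
                                          test = roles[["test"]]))
  distances <- stage("stats",
                     profile_distance_table(cube,
                                            reference = roles[["reference"]],
                                            test = roles[["test"]]))
  readr::write_tsv(dplyr::left_join(tests, distances, by = "protein_id"),
                   file.path(config$out_dir, "lane_tests.tsv"),
                   progress = FALSE)

  band_tests <- dplyr::bind_rows(lapply(names(config$windows), function(wn) {
    stage("stats", band_test(cube, wn, windows = config$windows,
                             reference = roles[["reference"]],
                             test = roles[["test"]]))
  }))
  readr::write_tsv(band_tests, file.path(config$out_dir, "band_tests.tsv"),
                   progress = FALSE)

  ratios <- stage("ratios", ratio_table(cube, windows = config$windows,
                                        policy = config$policy,
                                        reference = roles[["reference"]],
                                        test = roles[["test"]]))
  readr::write_tsv(ratios, file.path(config$out_dir, "ratio_table.tsv"),
                   progress = FALSE)

  complexes <- stats::na.omit(unique(cube$proteins$complex))
  summaries <- NULL
  if (length(complexes) > 0) {
    lane_ratios <- dplyr::filter(ratios, .data$scope == "whole-lane")
    rows <- lapply(complexes, function(cx) {
      members <- cube$proteins$protein_id[!is.na(cube$proteins$complex) &
                                            cube$proteins$complex == cx]
      summary <- tryCatch(
        complex_median_ratio(lane_ratios, members, name = cx),
        error = function(e) NULL
      )
      if (is.null(summary)) return(NULL)
      tibble::tibble(complex = cx, median_ratio = summary$median_ratio,
                     n_members_used = length(summary$members_used),
                     excluded = paste(names(summary$excluded), collapse = ","))
    })
    summaries <- dplyr::bind_rows(rows)
    readr::write_tsv(summaries,
                     file.path(config$out_dir, "complex_summaries.tsv"),
                     progress = FALSE)
  }

  candidates <- stage("screen",
                      flag_candidates(cube, config$screen,
                                      windows = config$windows,
                                      reference = roles[["reference"]],
                                      test = roles[["test"]]))
  readr::write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    dplyr::filter(candidates, .data$candidate),
    file.path(config$out_dir, "candidates.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )

  similarity <- NULL
  hits <- candidates$protein_id[candidates$candidate]
  refs <- intersect(config$reference_factors, cube_proteins(cube))
  if (length(hits) > 0 && length(refs) > 0) {
    similarity <- stage("screen",
                        rank_by_similarity(cube, hits, refs,
                                           strain = roles[["test"]]))
    sim_out <- tibble::as_tibble(similarity, rownames = "protein_id")
    readr::write_tsv(sim_out, file.path(config$out_dir, "similarity.tsv"),
                     progress = FALSE)
  }

  log_lines <- c(log_lines,
                 paste0("proteins analyzed: ", nrow(cube$proteins)),
                 paste0("candidates: ", sum(candidates$candidate)))
  writeLines(log_lines, log_path)

  invisible(list(cube = cube, normalization = normalization,
                 heatmaps = heatmaps, tests = tests, distances = distances,
                 band_tests = band_tests, ratios = ratios,
                 complex_summaries = summaries, candidates = candidates,
                 similarity = similarity))
}
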