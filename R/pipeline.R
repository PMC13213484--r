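#' Run the full screen pipeline on a simulated or loaded screen
#'
#' End-to-end orchestration: per-site tables are aggregated to well medians
#' per plate, robust features are selected from the first two replicate
#' plates (treated as the two biological repeats of the reference-plate
#' procedure), well profiles are collapsed to compound level across
#' replicates, Z-score fingerprints are computed against the vehicle
#' wells, and the metric tables (induction / activity / cell count,
#' cross-biosimilarity, region summaries) and optional cluster-match
#' report are assembled. When `out_dir` is given, every table is written
#' as delimited text together with the resolved parameters
#' (`run_config.json`), so a run is fully regenerable from its inputs.
#'
#' @param tables List of [feature_table()] (one per replicate plate).
#' @param layouts List of layout data frames aligned with `tables`.
#' @param selection Optional precomputed `feature_selection` (the
#'   once-per-screen selection from a reference-compound plate pair);
#'   overrides `select_features`.
#' @param select_features Perform robust-feature selection from plates 1
#'   and 2 (requires >= 2 plates); when `FALSE` all features are kept.
#'   Only meaningful when the plates carry reference compounds with real
#'   phenotypes — a null screen has no between-well signal to reproduce.
#' @param min_similarity Robust-feature similarity threshold.
#' @param change_threshold Absolute Z counting a feature as changed.
#' @param activity_threshold Induction (percent) above which a compound is
#'   called active.
#' @param cross_min_induction Induction filter for the cross-biosimilarity
#'   matrix.
#' @param scale_method Z-score scale: `"mad"` (robust) or `"sd"`.
#' @param cluster_lib Optional [cluster_library()] for subprofile matching
#'   (its feature space must match the selected features).
#' @param assign_threshold Cluster assignment threshold (percent).
#' @param out_dir Optional output directory for the result tables.
#' @return List of class `cpa_run`: `selection`, `profiles`
#'   (compound-level [well_profiles()]), `fingerprints`, `summary` (one
#'   row per fingerprint: induction, activity, relative cell count),
#'   `cross_biosimilarity` (or `NULL` when fewer than two fingerprints
#'   pass the filter), `region_summaries`, `cluster_matches` (or `NULL`),
#'   `params`.
#' @export
run_screen_pipeline <- function(tables, layouts,
                                selection = NULL,
                                select_features = FALSE,
                                min_similarity = 0.8,
                                change_threshold = 3,
                                activity_threshold = 5,
                                cross_min_induction = 30,
                                scale_method = c("mad", "sd"),
                                cluster_lib = NULL,
                                assign_threshold = 85,
                                out_dir = NULL) {
  scale_method <- match.arg(scale_method)
  stopifnot(length(tables) >= 1L, length(tables) == length(layouts))
  for (lay in layouts) {
    if (!any(lay$role == "vehicle")) {
      stop("plate layout without vehicle wells", call. = FALSE)
    }
  }
  per_plate <- Map(aggregate_sites, tables, layouts)

  if (is.null(selection) && select_features) {
    if (length(per_plate) < 2L) {
      stop("robust-feature selection needs >= 2 replicate plates",
           call. = FALSE)
    }
    selection <- select_robust_features(per_plate[[1L]], per_plate[[2L]],
                                        min_similarity = min_similarity)
  }
  if (!is.null(selection)) {
    if (!any(selection$selected)) {
      stop("no feature passed the reproducibility threshold ",
           min_similarity, call. = FALSE)
    }
    per_plate <- lapply(per_plate, apply_selection, selection)
  }

  profiles <- aggregate_replicates(per_plate)
  fingerprints <- build_fingerprints(profiles,
                                     change_threshold = change_threshold,
                                     scale_method = scale_method)

  summary_tab <- do.call(rbind, lapply(fingerprints, function(f) {
    data.frame(compound = f$compound,
               concentration_uM = f$concentration_uM,
               induction = f$induction,
               active = is_active(f$induction,
                                  threshold = activity_threshold),
               relative_cell_count = f$relative_cell_count,
               cell_count_class = f$cell_count_class,
               stringsAsFactors = FALSE)
  }))
  rownames(summary_tab) <- NULL

  cross <- tryCatch(
    cross_biosimilarity(fingerprints, min_induction = cross_min_induction),
    error = function(e) NULL
  )
  regions <- lapply(fingerprints, region_summary)
  matches <- if (!is.null(cluster_lib)) {
    lapply(fingerprints, match_clusters, library = cluster_lib,
           assign_threshold = assign_threshold)
  } else NULL

  params <- list(select_features = select_features,
                 min_similarity = min_similarity,
                 change_threshold = change_threshold,
                 activity_threshold = activity_threshold,
                 cross_min_induction = cross_min_induction,
                 scale_method = scale_method,
                 assign_threshold = assign_threshold,
                 n_selected_features = length(fingerprints[[1L]]$z))

  run <- structure(
    list(selection = selection, profiles = profiles,
         fingerprints = fingerprints, summary = summary_tab,
         cross_biosimilarity = cross, region_summaries = regions,
         cluster_matches = matches, params = params),
    class = "cpa_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.cpa_run <- function(x, ...) {
  cat("<cpa_run>", nrow(x$summary), "fingerprints over",
      x$params$n_selected_features, "features;",
      sum(x$summary$active), "active\n")
  invisible(x)
}

# persist every table of a pipeline run as delimited text + resolved config
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$selection)) {
    write_feature_selection(run$selection,
                            file.path(out_dir, "feature_selection.csv"))
  }
  write_fingerprints(run$fingerprints,
                     file.path(out_dir, "fingerprints.csv"))
  data.table::fwrite(run$summary, file.path(out_dir, "summary.csv"))
  if (!is.null(run$cross_biosimilarity)) {
    write_biosimilarity_matrix(run$cross_biosimilarity,
                               file.path(out_dir, "cross_biosimilarity.csv"))
  }
  reg <- do.call(rbind, Map(function(nm, tab) {
    cbind(profile = nm, tab, stringsAsFactors = FALSE)
  }, names(run$region_summaries), run$region_summaries))
  data.table::fwrite(reg, file.path(out_dir, "region_summaries.csv"))
  if (!is.null(run$cluster_matches)) {
    cm <- do.call(rbind, Map(function(nm, tab) {
      cbind(profile = nm, as.data.frame(tab), stringsAsFactors = FALSE)
    }, names(run$cluster_matches), run$cluster_matches))
    data.table::fwrite(cm, file.path(out_dir, "cluster_matches.csv"))
  }
  jsonlite::write_json(run$params, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
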