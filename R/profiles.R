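#' Well-level (or compound-level) profile collection
#'
#' Container pairing a metadata table with a matrix of aggregated feature
#' values, one row per profile. Produced by [aggregate_sites()] and
#' [aggregate_replicates()].
#'
#' @param meta Data frame with at least a `compound` column; typically also
#'   `well`, `concentration_uM`, `role` and `cell_count`.
#' @param values Numeric matrix with one row per profile and named feature
#'   columns.
#' @return An object of class `well_profiles`.
#' @export
well_profiles <- function(meta, values) {
  values <- as.matrix(values)
  stopifnot(nrow(meta) == nrow(values), !is.null(colnames(values)))
  structure(list(meta = as.data.frame(meta), values = values),
            class = "well_profiles")
}

#' @export
print.well_profiles <- function(x, ...) {
  cat("<well_profiles>", nrow(x$values), "profiles x", ncol(x$values),
      "features\n")
  invisible(x)
}

#' @export
`[.well_profiles` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  well_profiles(x$meta[i, , drop = FALSE], x$values[i, j, drop = FALSE])
}

#' Number of profiles / features
#' @param x A `well_profiles` object.
#' @export
dim.well_profiles <- function(x) dim(x$values)

#' Aggregate per-site features to well medians
#'
#' Collapses the imaging sites of each well (e.g. 9 sites to 1 well) by the
#' per-feature median, and likewise for the cell count. Missing site values
#' are ignored within each median; wells where a feature is missing at every
#' site stay missing and are recorded in the QC log (attribute `qc`).
#'
#' @param table A [feature_table()].
#' @param layout Optional plate layout data frame (`well`, `compound`,
#'   `concentration_uM`, `role`) used to annotate the profiles. Every well
#'   of the table must be present in the layout.
#' @return A [well_profiles()] object with one row per well, in plate order.
#' @export
aggregate_sites <- function(table, layout = NULL) {
  stopifnot(inherits(table, "feature_table"))
  dt <- data.table::as.data.table(table$values)
  dt[, `__well` := table$well]
  dt[, `__cc` := table$cell_count]
  feats <- colnames(table$values)
  agg <- dt[, lapply(.SD, median, na.rm = TRUE),
            by = `__well`, .SDcols = c(feats, "__cc")]
  vals <- as.matrix(agg[, feats, with = FALSE])
  vals[is.nan(vals)] <- NA_real_  # all-missing feature in a well
  rownames(vals) <- NULL
  meta <- data.frame(well = agg$`__well`, cell_count = agg$`__cc`,
                     stringsAsFactors = FALSE)
  if (!is.null(layout)) {
    lay <- as.data.frame(layout)
    idx <- match(meta$well, lay$well)
    if (anyNA(idx)) {
      stop("wells missing from layout: ",
           paste(head(meta$well[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    meta$compound <- lay$compound[idx]
    meta$concentration_uM <- lay$concentration_uM[idx]
    meta$role <- lay$role[idx]
  }
  qc <- which(is.na(vals), arr.ind = TRUE)
  out <- well_profiles(meta, vals)
  attr(out, "qc") <- if (nrow(qc)) {
    data.frame(well = meta$well[qc[, 1L]], feature = feats[qc[, 2L]],
               issue = "all sites missing", stringsAsFactors = FALSE)
  } else NULL
  out
}

#' Aggregate replicate plates to compound-level profiles
#'
#' Collapses well profiles from replicate plates to one profile per
#' (compound, concentration) pair by the element-wise median across plates.
#' Profiles are matched by compound identity, never by well coordinates, so
#' shifted plate layouts aggregate identically to unshifted ones. A
#' compound present on only a subset of plates is aggregated over the
#' plates that carry it, with a warning.
#'
#' @param profiles_per_plate List of [well_profiles()] objects (one per
#'   plate), each annotated with `compound` and `concentration_uM`.
#' @return A [well_profiles()] object with one row per (compound,
#'   concentration), ordered by first appearance on the first plate.
#' @export
aggregate_replicates <- function(profiles_per_plate) {
  stopifnot(length(profiles_per_plate) >= 1L,
            all(vapply(profiles_per_plate, inherits, logical(1L),
                       "well_profiles")))
  feats <- colnames(profiles_per_plate[[1L]]$values)
  for (p in profiles_per_plate) {
    if (is.null(p$meta$compound)) {
      stop("profiles must carry compound annotation (pass a layout to aggregate_sites)",
           call. = FALSE)
    }
    if (!identical(colnames(p$values), feats)) {
      stop("feature columns differ between plates", call. = FALSE)
    }
  }
  key_of <- function(p) paste(p$meta$compound, p$meta$concentration_uM,
                              sep = "@")
  keys <- lapply(profiles_per_plate, key_of)
  all_keys <- unique(unlist(keys))
  counts <- table(factor(unlist(lapply(keys, unique)), levels = all_keys))
  if (any(counts < length(profiles_per_plate))) {
    warning("compound(s) absent from some plates; aggregated over available plates: ",
            paste(head(names(counts)[counts < length(profiles_per_plate)], 5L),
                  collapse = ", "), call. = FALSE)
  }
  stacked_vals <- do.call(rbind, lapply(profiles_per_plate, `[[`, "values"))
  stacked_key <- unlist(keys)
  stacked_cc <- unlist(lapply(profiles_per_plate,
                              function(p) p$meta$cell_count %||%
                                rep(NA_real_, nrow(p$values))))
  dt <- data.table::as.data.table(stacked_vals)
  dt[, `__key` := stacked_key]
  dt[, `__cc` := stacked_cc]
  agg <- dt[, lapply(.SD, median, na.rm = TRUE),
            by = `__key`, .SDcols = c(feats, "__cc")]
  data.table::setkeyv(agg, NULL)
  agg <- agg[match(all_keys, agg$`__key`), ]
  vals <- as.matrix(agg[, feats, with = FALSE])
  vals[is.nan(vals)] <- NA_real_
  rownames(vals) <- NULL
  first_meta <- do.call(rbind, lapply(profiles_per_plate, `[[`, "meta"))
  idx <- match(all_keys, paste(first_meta$compound,
                               first_meta$concentration_uM, sep = "@"))
  meta <- data.frame(compound = first_meta$compound[idx],
                     concentration_uM = first_meta$concentration_uM[idx],
                     role = if (is.null(first_meta$role)) NA_character_
                            else first_meta$role[idx],
                     cell_count = as.numeric(agg$`__cc`),
                     stringsAsFactors = FALSE)
  well_profiles(meta, vals)
}

#' Z-score fingerprint of one profile against vehicle controls
#'
#' Computes the phenotypic fingerprint of a treated profile as the
#' per-feature Z-score relative to the median of the DMSO vehicle profiles,
#' using a robust scale (1.4826 x MAD of the vehicle wells) by default or
#' the plain SD. Features with zero vehicle dispersion are excluded from
#' the fingerprint (and from the induction denominator) and recorded in the
#' `excluded` field, never assigned infinite Z.
#'
#' @param profile A single-profile [well_profiles()] row (or a
#'   `well_profiles` object with one row).
#' @param vehicle_profiles [well_profiles()] of the vehicle wells (>= 3
#'   rows).
#' @param features Optional [feature_selection] or integer/character vector
#'   restricting the feature set; defaults to all features.
#' @param change_threshold Absolute Z at or beyond which a feature counts as
#'   significantly changed for the induction value.
#' @param scale_method `"mad"` (robust, default) or `"sd"`.
#' @param regions Optional named list of feature index vectors partitioning
#'   the selected features into the cell / cytoplasm / nuclei regions;
#'   defaults to [cpa_regions()] of the selected length.
#' @return An object of class `fingerprint`: fields `compound`,
#'   `concentration_uM`, `z` (named numeric), `induction` (percent),
#'   `relative_cell_count` (percent or `NA`), `cell_count_class`,
#'   `regions`, `excluded`, `n_vehicle`, `scale_method`,
#'   `change_threshold`.
#' @export
fingerprint <- function(profile, vehicle_profiles, features = NULL,
                        change_threshold = 3, scale_method = c("mad", "sd"),
                        regions = NULL) {
  scale_method <- match.arg(scale_method)
  stopifnot(inherits(profile, "well_profiles"),
            inherits(vehicle_profiles, "well_profiles"),
            nrow(profile$values) == 1L)
  if (nrow(vehicle_profiles$values) < 3L) {
    stop("need at least 3 vehicle profiles to estimate dispersion",
         call. = FALSE)
  }
  sel <- resolve_features(features, colnames(profile$values))
  x <- profile$values[1L, sel]
  veh <- vehicle_profiles$values[, sel, drop = FALSE]
  centre <- col_medians(veh)
  scale <- if (scale_method == "mad") {
    apply(veh, 2L, mad, na.rm = TRUE)
  } else {
    apply(veh, 2L, sd, na.rm = TRUE)
  }
  bad <- !is.finite(scale) | scale == 0 | !is.finite(x) | !is.finite(centre)
  z <- (x - centre) / scale
  z <- z[!bad]
  if (!length(z)) stop("no feature with estimable vehicle dispersion",
                       call. = FALSE)
  ind <- induction(z, change_threshold = change_threshold)
  rcc <- if (!is.null(profile$meta$cell_count) &&
             !is.null(vehicle_profiles$meta$cell_count)) {
    relative_cell_count(profile, vehicle_profiles)
  } else {
    list(percent = NA_real_, class = NA_character_)
  }
  if (is.null(regions)) regions <- cpa_regions(length(z))
  structure(
    list(compound = profile$meta$compound %||% NA_character_,
         concentration_uM = profile$meta$concentration_uM %||% NA_real_,
         z = z, induction = ind,
         relative_cell_count = rcc$percent,
         cell_count_class = rcc$class,
         regions = regions,
         excluded = names(x)[bad],
         n_vehicle = nrow(veh),
         scale_method = scale_method,
         change_threshold = change_threshold),
    class = "fingerprint"
  )
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s @ %s uM: %d features, induction %.1f%%, cell count %.0f%% (%s)\n",
              x$compound, format(x$concentration_uM), length(x$z),
              x$induction,
              x$relative_cell_count, x$cell_count_class))
  invisible(x)
}

# features argument -> integer/character index into feature names
resolve_features <- function(features, all_names) {
  if (is.null(features)) return(seq_along(all_names))
  if (inherits(features, "feature_selection")) {
    sel <- features$feature_index[features$selected]
    if (!length(sel)) stop("empty feature selection", call. = FALSE)
    if (any(sel > length(all_names))) {
      stop("feature selection index out of range", call. = FALSE)
    }
    return(sel)
  }
  if (is.character(features)) {
    idx <- match(features, all_names)
    if (anyNA(idx)) stop("unknown feature name(s): ",
                         paste(head(features[is.na(idx)]), collapse = ", "),
                         call. = FALSE)
    return(idx)
  }
  features <- as.integer(features)
  if (!length(features)) stop("empty feature selection", call. = FALSE)
  if (any(features < 1L | features > length(all_names))) {
    stop("feature index out of range", call. = FALSE)
  }
  features
}

#' Relative cell count of a treated profile versus vehicle
#'
#' Treated median cell count as a percentage of the vehicle median, with a
#' three-band classification: `normal` at 80% and above (the 100 +/- 20%
#' band), `reduced` in [50, 80), and `growth_arrest` below 50%.
#'
#' @param profile Single-row [well_profiles()] with a `cell_count` column.
#' @param vehicle_profiles Vehicle [well_profiles()] with `cell_count`.
#' @return List with `percent` and `class`.
#' @export
#' @examples
#' # a treated well at 40% of the vehicle count is in growth arrest
relative_cell_count <- function(profile, vehicle_profiles) {
  cc <- profile$meta$cell_count
  veh <- median(vehicle_profiles$meta$cell_count, na.rm = TRUE)
  if (!is.finite(veh) || veh <= 0) {
    stop("vehicle median cell count must be positive", call. = FALSE)
  }
  pct <- 100 * cc / veh
  cls <- if (is.na(pct)) NA_character_
  else if (pct >= 80) "normal"
  else if (pct >= 50) "reduced"
  else "growth_arrest"
  list(percent = pct, class = cls)
}

#' Fingerprints for every treatment profile of a screen
#'
#' Convenience wrapper: splits compound-level profiles into vehicle and
#' treatment rows by `role` and computes one [fingerprint()] per treatment
#' profile.
#'
#' @param profiles Compound-level [well_profiles()] (from
#'   [aggregate_replicates()]) with a `role` column.
#' @param features,change_threshold,scale_method,regions Passed to
#'   [fingerprint()].
#' @return Named list of `fingerprint` objects
#'   (`compound@concentration`).
#' @export
build_fingerprints <- function(profiles, features = NULL,
                               change_threshold = 3,
                               scale_method = c("mad", "sd"),
                               regions = NULL) {
  scale_method <- match.arg(scale_method)
  stopifnot(inherits(profiles, "well_profiles"),
            !is.null(profiles$meta$role))
  veh_idx <- which(profiles$meta$role == "vehicle")
  trt_idx <- which(profiles$meta$role != "vehicle")
  if (length(veh_idx) < 3L) stop("need >= 3 vehicle profiles", call. = FALSE)
  sel <- resolve_features(features, colnames(profiles$values))
  veh <- profiles$values[veh_idx, sel, drop = FALSE]
  centre <- col_medians(veh)
  scale <- if (scale_method == "mad") {
    apply(veh, 2L, mad, na.rm = TRUE)
  } else {
    apply(veh, 2L, sd, na.rm = TRUE)
  }
  veh_cc <- median(profiles$meta$cell_count[veh_idx], na.rm = TRUE)
  zmat <- sweep(sweep(profiles$values[trt_idx, sel, drop = FALSE],
                      2L, centre, `-`), 2L, scale, `/`)
  out <- lapply(seq_along(trt_idx), function(k) {
    i <- trt_idx[k]
    x <- profiles$values[i, sel]
    bad <- !is.finite(scale) | scale == 0 | !is.finite(x) |
      !is.finite(centre)
    z <- zmat[k, ][!bad]
    if (!length(z)) stop("no feature with estimable vehicle dispersion",
                         call. = FALSE)
    cc <- profiles$meta$cell_count[i]
    pct <- if (is.finite(veh_cc) && veh_cc > 0) 100 * cc / veh_cc
           else NA_real_
    cls <- if (is.na(pct)) NA_character_
    else if (pct >= 80) "normal" else if (pct >= 50) "reduced"
    else "growth_arrest"
    structure(
      list(compound = profiles$meta$compound[i],
           concentration_uM = profiles$meta$concentration_uM[i],
           z = z, induction = induction(z, change_threshold),
           relative_cell_count = pct, cell_count_class = cls,
           regions = regions %||% cpa_regions(length(z)),
           excluded = colnames(profiles$values)[sel][bad],
           n_vehicle = length(veh_idx), scale_method = scale_method,
           change_threshold = change_threshold),
      class = "fingerprint")
  })
  names(out) <- paste0(profiles$meta$compound[trt_idx], "@",
                       profiles$meta$concentration_uM[trt_idx])
  out
}
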