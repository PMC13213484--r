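#' Select reproducible features from two biological repeats
#'
#' For every feature, the profile over the whole plate — the vector of its
#' well-median values across all wells, matched by compound label — is
#' compared between two biological repeats. The similarity is the same
#' measure used for biosimilarity, 1 minus the Pearson correlation distance
#' clipped at 0, and a feature enters the robust set when its similarity is
#' at least `min_similarity`. Features that are constant in either repeat
#' have an undefined correlation and are rejected (recorded in the
#' `rejected_constant` attribute). Well vectors are the raw medians:
#' selection precedes Z-score normalisation in the workflow.
#'
#' @param plate_repeat_1,plate_repeat_2 [well_profiles()] of the same plate
#'   layout in two biological repeats (>= 3 wells; matched by `compound`).
#' @param min_similarity Similarity threshold (default 0.8).
#' @return An object of class `feature_selection`: a data frame with
#'   columns `feature_index`, `feature_name`, `similarity`, `selected`
#'   (original feature order preserved) and attribute `min_similarity`.
#' @export
select_robust_features <- function(plate_repeat_1, plate_repeat_2,
                                   min_similarity = 0.8) {
  stopifnot(inherits(plate_repeat_1, "well_profiles"),
            inherits(plate_repeat_2, "well_profiles"))
  feats <- colnames(plate_repeat_1$values)
  if (!identical(feats, colnames(plate_repeat_2$values))) {
    stop("repeats have different feature sets", call. = FALSE)
  }
  if (nrow(plate_repeat_1$values) < 3L) {
    stop("need at least 3 wells", call. = FALSE)
  }
  key1 <- plate_repeat_1$meta$compound
  key2 <- plate_repeat_2$meta$compound
  idx <- match(key1, key2)
  if (anyNA(idx)) {
    stop("repeats do not cover the same compounds", call. = FALSE)
  }
  v1 <- plate_repeat_1$values
  v2 <- plate_repeat_2$values[idx, , drop = FALSE]
  sd1 <- apply(v1, 2L, sd, na.rm = TRUE)
  sd2 <- apply(v2, 2L, sd, na.rm = TRUE)
  constant <- !is.finite(sd1) | !is.finite(sd2) | sd1 == 0 | sd2 == 0
  sim <- rep(NA_real_, length(feats))
  ok <- which(!constant)
  if (length(ok)) {
    # column-wise Pearson r between matched repeats
    r <- vapply(ok, function(j) {
      cor(v1[, j], v2[, j], use = "complete.obs")
    }, numeric(1L))
    sim[ok] <- pmax(0, r)
  }
  selected <- !is.na(sim) & sim >= min_similarity
  out <- data.frame(feature_index = seq_along(feats), feature_name = feats,
                    similarity = sim, selected = selected,
                    stringsAsFactors = FALSE)
  attr(out, "min_similarity") <- min_similarity
  attr(out, "rejected_constant") <- feats[constant]
  class(out) <- c("feature_selection", "data.frame")
  out
}

#' Restrict profiles to a robust feature selection
#'
#' Applies a [select_robust_features()] result (or an explicit index set)
#' to a `well_profiles` object or a feature matrix, so downstream analyses
#' see only the selected features. Applied once per screen.
#'
#' @param x A [well_profiles()] object or numeric matrix with feature
#'   columns.
#' @param selection A `feature_selection`, or integer/character feature
#'   indices.
#' @return Object of the same type restricted to the selected features, in
#'   original feature order.
#' @export
apply_selection <- function(x, selection) {
  idx <- if (inherits(selection, "feature_selection")) {
    selection$feature_index[selection$selected]
  } else if (is.character(selection)) {
    selection
  } else {
    as.integer(selection)
  }
  if (!length(idx)) stop("empty feature selection", call. = FALSE)
  if (inherits(x, "well_profiles")) {
    cols <- resolve_features(idx, colnames(x$values))
    return(x[, cols])
  }
  x <- as.matrix(x)
  cols <- resolve_features(idx, colnames(x))
  x[, cols, drop = FALSE]
}
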