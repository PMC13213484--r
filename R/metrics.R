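#' Induction value of a fingerprint
#'
#' Fraction of significantly changed features, in percent: the share of
#' features whose absolute Z-score reaches `change_threshold`.
#'
#' @param z Numeric Z-score vector over the selected features, or a
#'   [fingerprint] object.
#' @param change_threshold Absolute Z at or beyond which a feature counts
#'   as changed (default 3, the conventional robust-Z significance cut).
#' @return Induction in percent, in `[0, 100]`.
#' @export
#' @examples
#' induction(c(0, 4, -5, 1))  # 50
induction <- function(z, change_threshold = 3) {
  if (inherits(z, "fingerprint")) z <- z$z
  z <- as.numeric(z)
  if (!length(z)) stop("empty feature set", call. = FALSE)
  if (!all(is.finite(z))) stop("non-finite Z-scores", call. = FALSE)
  100 * sum(abs(z) >= change_threshold) / length(z)
}

#' Biological activity call
#'
#' A compound is considered biologically active when its induction value
#' exceeds 5 percent (strictly).
#'
#' @param induction Induction value(s) in percent.
#' @param threshold Activity threshold in percent.
#' @return Logical vector.
#' @export
is_active <- function(induction, threshold = 5) {
  stopifnot(all(induction >= 0 & induction <= 100, na.rm = TRUE))
  induction > threshold
}

#' Biosimilarity of two fingerprints
#'
#' Similarity derived from the Pearson correlation distance CD = 1 - r:
#' biosimilarity = 1 - CD = r, clipped at 0 from below and expressed in
#' percent, so anti-correlated profiles score 0 and identical profiles 100.
#'
#' @param z_a,z_b Numeric Z-score vectors of equal length (>= 3), or
#'   [fingerprint] objects over the same feature set.
#' @return Percent in `[0, 100]`, or `NA` (with a warning) when either
#'   vector is constant and the correlation undefined.
#' @export
#' @examples
#' biosimilarity(c(1, 2, 3, 4), c(1, 2, 3, 5))  # ~98.26
biosimilarity <- function(z_a, z_b) {
  if (inherits(z_a, "fingerprint")) z_a <- z_a$z
  if (inherits(z_b, "fingerprint")) z_b <- z_b$z
  z_a <- as.numeric(z_a); z_b <- as.numeric(z_b)
  if (length(z_a) != length(z_b)) {
    stop("fingerprints have different lengths", call. = FALSE)
  }
  if (length(z_a) < 3L) stop("need at least 3 features", call. = FALSE)
  if (sd(z_a) == 0 || sd(z_b) == 0) {
    warning("constant profile: biosimilarity undefined", call. = FALSE)
    return(NA_real_)
  }
  if (identical(z_a, z_b)) return(100)  # self-similarity is exact
  100 * max(0, cor(z_a, z_b))
}

#' Cross-biosimilarity matrix of active fingerprints
#'
#' Pairwise biosimilarity among the fingerprints whose induction exceeds
#' `min_induction` (default 30 percent, the activity filter used for
#' cross-comparisons). Symmetric with a diagonal of 100.
#'
#' @param fingerprints List of [fingerprint] objects over the same feature
#'   set.
#' @param min_induction Induction filter in percent (strict).
#' @return Object of class `biosimilarity_matrix`: a symmetric numeric
#'   matrix of percents labelled `compound@concentration`.
#' @export
cross_biosimilarity <- function(fingerprints, min_induction = 30) {
  stopifnot(length(fingerprints) >= 1L,
            all(vapply(fingerprints, inherits, logical(1L), "fingerprint")))
  keep <- vapply(fingerprints, function(f) f$induction > min_induction,
                 logical(1L))
  fps <- fingerprints[keep]
  if (length(fps) < 2L) {
    stop("fewer than 2 fingerprints pass the induction > ", min_induction,
         "% filter", call. = FALSE)
  }
  labs <- vapply(fps, function(f) paste0(f$compound, "@",
                                         format(f$concentration_uM)),
                 character(1L))
  n <- length(fps)
  m <- matrix(100, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- biosimilarity(fps[[i]], fps[[j]])
    }
  }
  structure(m, class = c("biosimilarity_matrix", "matrix", "array"))
}

#' Default region partition of the selected feature set
#'
#' Partitions feature indices 1..n into the three morphological regions of
#' a fingerprint — cell, cytoplasm and nuclei. For the canonical 579-feature
#' robust set the boundaries are cell 1-229, cytoplasm 230-461, nuclei
#' 462-579; other lengths split proportionally to those block sizes.
#'
#' @param n Number of selected features.
#' @return Named list of integer index vectors covering 1..n exactly once.
#' @export
#' @examples
#' lengths(cpa_regions(579))
cpa_regions <- function(n) {
  stopifnot(n >= 3L)
  b1 <- min(max(1L, round(229 / 579 * n)), n - 2L)
  b2 <- min(max(b1 + 1L, round(461 / 579 * n)), n - 1L)
  list(cell = seq_len(b1),
       cytoplasm = seq.int(b1 + 1L, b2),
       nuclei = seq.int(b2 + 1L, n))
}

#' Region summary of a fingerprint
#'
#' Mean absolute Z and the count of changed features per morphological
#' region (cell / cytoplasm / nuclei), supporting statements such as a
#' profile being more strongly changed in the cytoplasm block than the
#' nuclei block.
#'
#' @param fp A [fingerprint] (its `regions` field defines the partition).
#' @param change_threshold Absolute Z counting a feature as changed;
#'   defaults to the fingerprint's own threshold.
#' @return Data frame with columns `region`, `n_features`, `mean_abs_z`,
#'   `n_changed`.
#' @export
region_summary <- function(fp, change_threshold = NULL) {
  stopifnot(inherits(fp, "fingerprint"))
  thr <- change_threshold %||% fp$change_threshold
  regions <- fp$regions
  idx_all <- sort(unlist(regions, use.names = FALSE))
  if (!identical(idx_all, seq_along(fp$z))) {
    stop("regions do not partition the fingerprint features", call. = FALSE)
  }
  do.call(rbind, lapply(names(regions), function(r) {
    zz <- fp$z[regions[[r]]]
    data.frame(region = r, n_features = length(zz),
               mean_abs_z = mean(abs(zz)),
               n_changed = sum(abs(zz) >= thr),
               stringsAsFactors = FALSE)
  }))
}

#' Most strongly changed features of a fingerprint
#'
#' Features whose absolute Z-score reaches `min_abs`, ordered by decreasing
#' absolute Z; ties are broken by ascending feature index.
#'
#' @param fp A [fingerprint] or a named Z vector.
#' @param min_abs Absolute Z cut (default 10).
#' @return Data frame with columns `feature_index`, `feature`, `z`;
#'   zero rows when nothing passes.
#' @export
top_changed <- function(fp, min_abs = 10) {
  z <- if (inherits(fp, "fingerprint")) fp$z else as.numeric(fp)
  nm <- names(z) %||% as.character(seq_along(z))
  idx <- which(abs(z) >= min_abs)
  ord <- idx[order(-abs(z[idx]), idx)]
  data.frame(feature_index = ord, feature = nm[ord], z = unname(z[ord]),
             stringsAsFactors = FALSE)
}
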