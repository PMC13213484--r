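#' Bioactivity cluster library
#'
#' A library of named bioactivity clusters. Each cluster carries the
#' fingerprints of its member reference compounds (a matrix with one row
#' per member over the full selected feature set) and the index set of its
#' dominant features — the subprofile features that characterise the
#' cluster's mode of action. Dominant features are library content supplied
#' with the clusters, not computed here.
#'
#' @param clusters Named list; each element a list with `members` (numeric
#'   matrix, rownames = reference compound names) and `dominant` (integer
#'   feature indices).
#' @param feature_names Character vector naming the shared feature space.
#' @return An object of class `cluster_library`.
#' @export
cluster_library <- function(clusters, feature_names) {
  stopifnot(length(clusters) >= 1L, !is.null(names(clusters)))
  for (nm in names(clusters)) {
    cl <- clusters[[nm]]
    cl$members <- as.matrix(cl$members)
    if (nrow(cl$members) < 1L) stop("cluster '", nm, "' has no members",
                                    call. = FALSE)
    if (ncol(cl$members) != length(feature_names)) {
      stop("cluster '", nm, "' members do not match the feature space",
           call. = FALSE)
    }
    dom <- as.integer(cl$dominant)
    if (!length(dom)) stop("cluster '", nm, "' has an empty dominant set",
                           call. = FALSE)
    if (any(dom < 1L | dom > length(feature_names))) {
      stop("cluster '", nm, "' dominant features outside the feature space",
           call. = FALSE)
    }
    if (is.null(rownames(cl$members))) {
      rownames(cl$members) <- paste0(nm, "_ref", seq_len(nrow(cl$members)))
    }
    clusters[[nm]] <- list(members = cl$members, dominant = sort(dom))
  }
  structure(list(clusters = clusters,
                 feature_names = as.character(feature_names)),
            class = "cluster_library")
}

#' @export
print.cluster_library <- function(x, ...) {
  cat("<cluster_library>", length(x$clusters), "clusters over",
      length(x$feature_names), "features:\n ",
      paste(names(x$clusters), collapse = ", "), "\n")
  invisible(x)
}

#' Subprofile of a bioactivity cluster
#'
#' The cluster subprofile is the element-wise median of the member
#' fingerprints restricted to the cluster's dominant features.
#'
#' @param members Numeric matrix of member Z-vectors (rows = members) or a
#'   list of [fingerprint] objects.
#' @param dominant_features Integer indices of the dominant features.
#' @return Named numeric vector of length `length(dominant_features)`.
#' @export
build_cluster_subprofile <- function(members, dominant_features) {
  if (is.list(members) && all(vapply(members, inherits, logical(1L),
                                     "fingerprint"))) {
    members <- do.call(rbind, lapply(members, `[[`, "z"))
  }
  members <- as.matrix(members)
  dominant_features <- as.integer(dominant_features)
  if (!length(dominant_features)) stop("empty dominant feature set",
                                       call. = FALSE)
  if (any(dominant_features < 1L | dominant_features > ncol(members))) {
    stop("dominant feature index out of range", call. = FALSE)
  }
  sub <- members[, dominant_features, drop = FALSE]
  out <- col_medians(sub)
  names(out) <- colnames(members)[dominant_features] %||%
    as.character(dominant_features)
  out
}

#' Match a fingerprint against a cluster library
#'
#' For each cluster, the fingerprint is restricted to the cluster's
#' dominant features and its biosimilarity to the cluster subprofile is
#' computed; the fingerprint is assigned to a cluster when that similarity
#' strictly exceeds `assign_threshold` (default 85 percent). A fingerprint
#' below the threshold for every cluster is the "unknown cluster" outcome.
#' The nearest reference compound over the full profile is reported as
#' well.
#'
#' @param fp A [fingerprint] over the same selected feature space as the
#'   library.
#' @param library A [cluster_library()].
#' @param assign_threshold Assignment threshold in percent.
#' @return Object of class `cluster_match_report`: a data frame with one
#'   row per cluster (`cluster`, `subprofile_biosimilarity`, `assigned`,
#'   `best_reference`, `reference_biosimilarity`), ordered by decreasing
#'   subprofile biosimilarity, with attributes `compound`, `assigned_to`
#'   (character(0) if unassigned) and `assign_threshold`.
#' @export
match_clusters <- function(fp, library, assign_threshold = 85) {
  stopifnot(inherits(fp, "fingerprint"), inherits(library, "cluster_library"))
  if (length(fp$z) != length(library$feature_names)) {
    stop("fingerprint feature space does not match the cluster library (",
         length(fp$z), " vs ", length(library$feature_names), " features)",
         call. = FALSE)
  }
  rows <- lapply(names(library$clusters), function(nm) {
    cl <- library$clusters[[nm]]
    sub <- build_cluster_subprofile(cl$members, cl$dominant)
    sim <- biosimilarity(fp$z[cl$dominant], sub)
    ref_sims <- apply(cl$members, 1L, function(m) biosimilarity(fp$z, m))
    best <- which.max(ref_sims)
    data.frame(cluster = nm,
               subprofile_biosimilarity = sim,
               assigned = isTRUE(sim > assign_threshold),
               best_reference = rownames(cl$members)[best],
               reference_biosimilarity = ref_sims[best],
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report <- report[order(-report$subprofile_biosimilarity, report$cluster), ]
  rownames(report) <- NULL
  attr(report, "compound") <- fp$compound
  attr(report, "assigned_to") <- report$cluster[report$assigned]
  attr(report, "assign_threshold") <- assign_threshold
  class(report) <- c("cluster_match_report", "data.frame")
  report
}

#' Synthetic bioactivity cluster library
#'
#' Builds a synthetic library for testing and simulation, named after the
#' thirteen canonical mode-of-action clusters of reference cell painting
#' screens (AKT/PI3K/MTOR, aurora kinase, BET, DNA synthesis, HDAC, HSP90,
#' LCH, mitochondrial stress, Na+/K+ ATPase, protein synthesis, pyrimidine
#' synthesis, tubulin, uncoupler). Member fingerprints are random draws
#' around a cluster-specific archetype; no equivalence to the real
#' published clusters is implied.
#'
#' @param n_features Length of the selected feature space.
#' @param n_members Members per cluster.
#' @param n_dominant Dominant features per cluster.
#' @param signal_sd SD of the archetype Z values on dominant features.
#' @param member_noise_sd SD of member deviation from the archetype.
#' @param seed Integer seed.
#' @return A [cluster_library()].
#' @export
synthetic_cluster_library <- function(n_features = 579L, n_members = 3L,
                                      n_dominant = 60L, signal_sd = 5,
                                      member_noise_sd = 0.5, seed = 1L) {
  stopifnot(n_dominant <= n_features, n_members >= 1L)
  set.seed(seed)
  cluster_names <- c("AKT_PI3K_MTOR", "aurora_kinase", "BET",
                     "DNA_synthesis", "HDAC", "HSP90", "LCH",
                     "mitochondrial_stress", "Na_K_ATPase",
                     "protein_synthesis", "pyrimidine_synthesis",
                     "tubulin", "uncoupler")
  feats <- default_feature_names(n_features)
  clusters <- lapply(cluster_names, function(nm) {
    dominant <- sort(sample.int(n_features, n_dominant))
    archetype <- rnorm(n_features, sd = 0.5)
    archetype[dominant] <- rnorm(n_dominant, sd = signal_sd)
    members <- t(vapply(seq_len(n_members), function(i) {
      archetype + rnorm(n_features, sd = member_noise_sd)
    }, numeric(n_features)))
    colnames(members) <- feats
    rownames(members) <- paste0(nm, "_ref", seq_len(n_members))
    list(members = members, dominant = dominant)
  })
  names(clusters) <- cluster_names
  cluster_library(clusters, feats)
}
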