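#' Read / write per-site feature tables
#'
#' Delimited text with a header row and columns
#' `plate,well,site,cell_count,<feature names...>`; wells in letter-number
#' format (A01-P24 for a 384-well plate).
#'
#' @param path File path.
#' @return `read_feature_table()` returns a [feature_table()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = TRUE)
  need <- c("plate", "well", "site", "cell_count")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("malformed feature table '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  feats <- setdiff(names(dt), need)
  if (!length(feats)) stop("feature table '", path, "' has no feature columns",
                           call. = FALSE)
  plate <- unique(dt$plate)
  if (length(plate) != 1L) stop("feature table '", path,
                                "' mixes plates: ",
                                paste(plate, collapse = ", "), call. = FALSE)
  feature_table(plate_id = plate, well = dt$well, site = dt$site,
                cell_count = dt$cell_count,
                values = as.matrix(dt[, feats, with = FALSE]))
}

#' @rdname read_feature_table
#' @param table A [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  dt <- data.table::data.table(plate = table$plate_id, well = table$well,
                               site = table$site,
                               cell_count = table$cell_count)
  dt <- cbind(dt, data.table::as.data.table(table$values))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read / write plate layouts
#'
#' Delimited text `plate,well,compound,concentration_uM,role` with role in
#' vehicle / treatment / reference.
#'
#' @param path File path.
#' @return `read_plate_layout()` returns a data frame.
#' @export
read_plate_layout <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  need <- c("plate", "well", "compound", "concentration_uM", "role")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("malformed plate layout '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(dt$role), c("vehicle", "treatment", "reference"))
  if (length(bad)) stop("plate layout '", path, "': unknown role(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!any(dt$role == "vehicle")) {
    stop("plate layout '", path, "' has no vehicle wells", call. = FALSE)
  }
  dt[need]
}

#' @rdname read_plate_layout
#' @param layout Layout data frame.
#' @export
write_plate_layout <- function(layout, path) {
  data.table::fwrite(layout, path)
  invisible(path)
}

#' Write / read a fingerprint store
#'
#' One row per (compound, concentration): metadata columns (`compound`,
#' `concentration_uM`, `induction`, `relative_cell_count`,
#' `cell_count_class`, `active`) followed by the selected feature Z-scores.
#' The region partition and scoring parameters go to a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param fingerprints Named list of [fingerprint] objects over one shared
#'   feature set.
#' @param path File path for the delimited table.
#' @return `write_fingerprints()` returns `path` invisibly;
#'   `read_fingerprints()` returns the list of fingerprints.
#' @export
write_fingerprints <- function(fingerprints, path) {
  stopifnot(length(fingerprints) >= 1L,
            all(vapply(fingerprints, inherits, logical(1L), "fingerprint")))
  feats <- names(fingerprints[[1L]]$z)
  rows <- lapply(fingerprints, function(f) {
    if (!identical(names(f$z), feats)) {
      stop("fingerprints cover different feature sets", call. = FALSE)
    }
    c(list(compound = f$compound, concentration_uM = f$concentration_uM,
           induction = f$induction,
           relative_cell_count = f$relative_cell_count,
           cell_count_class = f$cell_count_class,
           active = is_active(f$induction)),
      as.list(f$z))
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path)
  f1 <- fingerprints[[1L]]
  meta <- list(feature_names = feats,
               regions = lapply(f1$regions, as.integer),
               scale_method = f1$scale_method,
               change_threshold = f1$change_threshold,
               n_vehicle = f1$n_vehicle)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  feats <- meta$feature_names
  missing_cols <- setdiff(feats, names(dt))
  if (length(missing_cols)) {
    stop("fingerprint store '", path, "' missing feature column(s): ",
         paste(head(missing_cols), collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(dt)), function(i) {
    structure(
      list(compound = dt$compound[i],
           concentration_uM = dt$concentration_uM[i],
           z = setNames(as.numeric(dt[i, feats]), feats),
           induction = dt$induction[i],
           relative_cell_count = dt$relative_cell_count[i],
           cell_count_class = dt$cell_count_class[i],
           regions = lapply(meta$regions, as.integer),
           excluded = character(0L),
           n_vehicle = meta$n_vehicle,
           scale_method = meta$scale_method,
           change_threshold = meta$change_threshold),
      class = "fingerprint")
  })
  names(out) <- paste0(dt$compound, "@", dt$concentration_uM)
  out
}

#' Write / read a robust feature selection
#'
#' Delimited text `feature_index,feature_name,similarity,selected`.
#'
#' @param selection A `feature_selection` from [select_robust_features()].
#' @param path File path.
#' @export
write_feature_selection <- function(selection, path) {
  stopifnot(inherits(selection, "feature_selection"))
  data.table::fwrite(as.data.frame(selection), path)
  invisible(path)
}

#' @rdname write_feature_selection
#' @export
read_feature_selection <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  need <- c("feature_index", "feature_name", "similarity", "selected")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("malformed feature selection '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  class(dt) <- c("feature_selection", "data.frame")
  dt
}

#' Write / read a cluster library
#'
#' The library is stored as a JSON metadata file (cluster names, member
#' names, dominant feature indices, feature names) plus one delimited
#' member-fingerprint table per cluster next to it
#' (`<stem>_<cluster>.csv`).
#'
#' @param library A [cluster_library()].
#' @param path Path of the metadata JSON file; per-cluster tables are
#'   written beside it.
#' @export
write_cluster_library <- function(library, path) {
  stopifnot(inherits(library, "cluster_library"))
  stem <- sub("\\.json$", "", path)
  meta <- list(
    feature_names = library$feature_names,
    clusters = lapply(names(library$clusters), function(nm) {
      cl <- library$clusters[[nm]]
      list(name = nm, members = rownames(cl$members),
           dominant = as.integer(cl$dominant),
           table = basename(paste0(stem, "_", nm, ".csv")))
    })
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (nm in names(library$clusters)) {
    cl <- library$clusters[[nm]]
    dt <- data.table::data.table(member = rownames(cl$members))
    dt <- cbind(dt, data.table::as.data.table(cl$members))
    data.table::fwrite(dt, paste0(stem, "_", nm, ".csv"))
  }
  invisible(path)
}

#' @rdname write_cluster_library
#' @export
read_cluster_library <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- meta$feature_names
  cl_meta <- meta$clusters
  clusters <- lapply(seq_len(nrow(cl_meta)), function(i) {
    tab <- data.table::fread(file.path(dirname(path), cl_meta$table[i]),
                             sep = ",", header = TRUE, data.table = FALSE)
    members <- as.matrix(tab[, feats, drop = FALSE])
    rownames(members) <- tab$member
    dom <- if (is.matrix(cl_meta$dominant)) cl_meta$dominant[i, ]
           else cl_meta$dominant[[i]]
    list(members = members, dominant = as.integer(dom))
  })
  names(clusters) <- cl_meta$name
  cluster_library(clusters, feats)
}

#' Read / write qPCR Ct tables
#'
#' Delimited text `sample,group,gene,replicate,ct`; the target and
#' reference genes are carried as attributes.
#'
#' @param path File path.
#' @param target_gene,reference_genes,control_group Gene/group designation
#'   attached to the returned table.
#' @export
read_qpcr_table <- function(path, target_gene, reference_genes,
                            control_group = "control") {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  need <- c("sample", "group", "gene", "replicate", "ct")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("malformed qPCR table '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  structure(dt[need], target_gene = target_gene,
            reference_genes = reference_genes,
            control_group = control_group,
            class = c("qpcr_table", "data.frame"))
}

#' @rdname read_qpcr_table
#' @param table A qPCR table.
#' @export
write_qpcr_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}

#' Write a biosimilarity matrix
#'
#' Delimited text with the profile labels as first column and header.
#'
#' @param m A `biosimilarity_matrix` from [cross_biosimilarity()].
#' @param path File path.
#' @export
write_biosimilarity_matrix <- function(m, path) {
  dt <- data.table::data.table(profile = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(unclass(m)))
  data.table::fwrite(dt, path)
  invisible(path)
}
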