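#' Define a phenotype signature for the plate simulator
#'
#' A signature is a sparse pattern of feature shifts that a compound imprints
#' on the morphological profile. Effect sizes are expressed in units of the
#' DMSO robust SD at the well-median level, i.e. the robust spread of vehicle
#' well medians within one plate, so a programmed effect of 5 shifts the
#' affected well medians five null spreads away from the vehicle centre.
#'
#' @param name Signature label.
#' @param affected_features Integer indices of the affected features.
#' @param effect_sizes Numeric vector of shifts (robust-SD units), recycled
#'   to `length(affected_features)`.
#' @param concentration_scaling Optional named numeric vector mapping a
#'   concentration (as character, in uM) to a multiplier on the effect
#'   sizes. Unlisted concentrations use multiplier 1.
#' @return An object of class `phenotype_signature`.
#' @export
#' @examples
#' phenotype_signature("tubulin-like", 1:20, 5)
phenotype_signature <- function(name, affected_features, effect_sizes,
                                concentration_scaling = NULL) {
  affected_features <- as.integer(affected_features)
  stopifnot(length(affected_features) >= 1L, !anyNA(affected_features),
            all(affected_features >= 1L), all(is.finite(effect_sizes)))
  effect_sizes <- rep_len(as.numeric(effect_sizes), length(affected_features))
  if (!is.null(concentration_scaling)) {
    stopifnot(is.numeric(concentration_scaling),
              !is.null(names(concentration_scaling)))
  }
  structure(
    list(name = as.character(name),
         affected_features = affected_features,
         effect_sizes = effect_sizes,
         concentration_scaling = concentration_scaling),
    class = "phenotype_signature"
  )
}

signature_multiplier <- function(sig, concentration) {
  cs <- sig$concentration_scaling
  if (is.null(cs)) return(1)
  key <- as.character(concentration)
  if (key %in% names(cs)) unname(cs[key]) else 1
}

#' Configure a synthetic cell painting screen
#'
#' Describes a screen of replicate 384-well-style plates with per-site
#' feature extraction. The null model draws each feature from a Gaussian
#' with feature-specific location and scale fixed once per screen; treated
#' wells are shifted by their signature effects; each plate carries an
#' additive per-feature offset (the plate effect that shifted layouts are
#' meant to average out); optionally a fraction of features is made
#' irreproducible between replicates by dominant per-plate well noise.
#'
#' @param n_features Number of extracted features per site.
#' @param n_wells Wells per plate (24, 96, 384 or 1536).
#' @param sites_per_well Imaging sites per well.
#' @param n_replicate_plates Number of replicate plates.
#' @param vehicle_fraction Fraction of wells carrying DMSO vehicle.
#' @param signatures List of [phenotype_signature()] objects.
#' @param compounds Optional data frame with columns `compound`,
#'   `concentration_uM`, `signature` (name or `NA`) and optionally
#'   `toxicity` (multiplier on cell count, default 1). When `NULL`, every
#'   treatment well receives a distinct inert compound at 10 uM.
#' @param site_noise_sd Per-site noise SD in units of the feature scale.
#' @param plate_offset_sd SD of the additive per-(plate, feature) offset in
#'   units of the feature scale.
#' @param irreproducible_fraction Fraction of features whose per-plate well
#'   values are dominated by independent noise (used to exercise robust
#'   feature selection).
#' @param layout_shift Cyclically permute compound positions between
#'   replicate plates.
#' @param baseline_cells_per_site Mean vehicle cell count per imaging site.
#' @param cell_count_cv Coefficient of variation of the per-site cell count.
#' @param seed Integer seed; the whole screen is deterministic given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_features = 1716L,
                              n_wells = 384L,
                              sites_per_well = 9L,
                              n_replicate_plates = 3L,
                              vehicle_fraction = 0.1,
                              signatures = list(),
                              compounds = NULL,
                              site_noise_sd = 1,
                              plate_offset_sd = 0.2,
                              irreproducible_fraction = 0,
                              layout_shift = TRUE,
                              baseline_cells_per_site = 180,
                              cell_count_cv = 0.1,
                              seed = 1L) {
  stopifnot(n_features >= 1L, sites_per_well >= 1L, n_replicate_plates >= 1L,
            vehicle_fraction > 0, vehicle_fraction < 1,
            site_noise_sd >= 0, plate_offset_sd >= 0,
            irreproducible_fraction >= 0, irreproducible_fraction <= 1)
  well_names(n_wells)  # validates the plate format
  if (length(signatures)) {
    ok <- vapply(signatures, inherits, logical(1L), "phenotype_signature")
    if (!all(ok)) stop("signatures must be phenotype_signature objects",
                       call. = FALSE)
    names(signatures) <- vapply(signatures, `[[`, character(1L), "name")
    for (sig in signatures) {
      if (any(sig$affected_features > n_features)) {
        stop("signature '", sig$name, "' references feature index beyond n_features",
             call. = FALSE)
      }
    }
  }
  if (!is.null(compounds)) {
    compounds <- as.data.frame(compounds)
    stopifnot(all(c("compound", "concentration_uM", "signature") %in%
                    names(compounds)))
    if (is.null(compounds$toxicity)) compounds$toxicity <- 1
    unknown <- setdiff(stats::na.omit(unique(compounds$signature)),
                       names(signatures))
    if (length(unknown)) {
      stop("compounds reference unknown signature(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_features = as.integer(n_features), n_wells = as.integer(n_wells),
         sites_per_well = as.integer(sites_per_well),
         n_replicate_plates = as.integer(n_replicate_plates),
         vehicle_fraction = vehicle_fraction, signatures = signatures,
         compounds = compounds, site_noise_sd = site_noise_sd,
         plate_offset_sd = plate_offset_sd,
         irreproducible_fraction = irreproducible_fraction,
         layout_shift = isTRUE(layout_shift),
         baseline_cells_per_site = baseline_cells_per_site,
         cell_count_cv = cell_count_cv, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Per-site feature table for one plate
#'
#' @param plate_id Plate label.
#' @param well Character vector of well labels, one per row.
#' @param site Integer vector of site indices, one per row.
#' @param cell_count Numeric vector of per-site cell counts.
#' @param values Numeric matrix, rows aligned with `well`/`site`, one column
#'   per feature (column names are the feature names).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(plate_id, well, site, cell_count, values) {
  values <- as.matrix(values)
  stopifnot(length(well) == nrow(values), length(site) == nrow(values),
            length(cell_count) == nrow(values),
            !is.null(colnames(values)))
  key <- paste(well, site)
  if (anyDuplicated(key)) stop("duplicate (well, site) rows", call. = FALSE)
  structure(
    list(plate_id = as.character(plate_id), well = as.character(well),
         site = as.integer(site), cell_count = as.numeric(cell_count),
         values = values),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> plate", x$plate_id, "-", length(unique(x$well)),
      "wells,", max(x$site), "sites/well,", ncol(x$values), "features\n")
  invisible(x)
}

default_feature_names <- function(n) sprintf("F%04d", seq_len(n))

#' Simulate a cell painting screen with known ground truth
#'
#' Generates one per-site feature table and layout per replicate plate.
#' Vehicle wells follow the null model; treated wells are shifted by their
#' signature effects scaled by the concentration multiplier. Replicate
#' plates share compound assignments but (optionally) at cyclically shifted
#' well positions, and each plate carries its own additive per-feature
#' offset. Deterministic for a fixed `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `cpa_screen` with elements `tables` (list of
#'   [feature_table()]), `layouts` (list of data frames with columns
#'   `plate`, `well`, `compound`, `concentration_uM`, `role`), `truth`
#'   (ground-truth list, see Details) and `config`.
#' @details `truth$compounds` records, per compound, the signature, the
#'   programmed active-feature fraction and the toxicity multiplier;
#'   `truth$expected_z` holds the expected fingerprint Z of every compound
#'   and feature (effect divided by the replicate-median noise factor);
#'   `truth$feature_class` marks each feature `"stable"` or `"noisy"`.
#' @export
#' @examples
#' scr <- simulate_screen(simulation_config(n_features = 20, n_wells = 24,
#'                                          sites_per_well = 3, seed = 7))
#' scr$tables[[1]]
simulate_screen <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nf <- config$n_features
  nw <- config$n_wells
  ns <- config$sites_per_well
  np <- config$n_replicate_plates
  wells <- well_names(nw)
  feats <- default_feature_names(nf)

  # screen-level feature parameters: heterogeneous locations and scales
  mu <- rnorm(nf, mean = 10, sd = 3)
  sigma <- exp(rnorm(nf, mean = 0, sd = 0.4))
  n_noisy <- round(config$irreproducible_fraction * nf)
  feature_class <- rep("stable", nf)
  if (n_noisy > 0) feature_class[sample.int(nf, n_noisy)] <- "noisy"

  # compound assignment: one well per compound, vehicle wells carry unique
  # pseudo-compound labels so replicate matching keeps them distinct
  n_vehicle <- max(1L, round(config$vehicle_fraction * nw))
  if (n_vehicle >= nw) stop("vehicle_fraction leaves no treatment wells",
                            call. = FALSE)
  n_treat <- nw - n_vehicle
  cmp <- config$compounds
  if (is.null(cmp)) {
    cmp <- data.frame(compound = sprintf("CPD_%04d", seq_len(n_treat)),
                      concentration_uM = 10, signature = NA_character_,
                      toxicity = 1)
  } else if (nrow(cmp) > n_treat) {
    stop("more compounds than treatment wells", call. = FALSE)
  } else if (nrow(cmp) < n_treat) {
    n_fill <- n_treat - nrow(cmp)
    cmp <- rbind(cmp[, c("compound", "concentration_uM", "signature",
                         "toxicity")],
                 data.frame(compound = sprintf("CPD_%04d", seq_len(n_fill)),
                            concentration_uM = 10,
                            signature = NA_character_, toxicity = 1))
  }
  vehicle_pos <- sort(sample.int(nw, n_vehicle))
  assignment <- data.frame(
    compound = NA_character_, concentration_uM = NA_real_,
    role = "treatment", stringsAsFactors = FALSE
  )[rep(1L, nw), ]
  assignment$compound[vehicle_pos] <- paste0("DMSO_", wells[vehicle_pos])
  assignment$concentration_uM[vehicle_pos] <- 0
  assignment$role[vehicle_pos] <- "vehicle"
  treat_pos <- setdiff(seq_len(nw), vehicle_pos)
  assignment$compound[treat_pos] <- cmp$compound
  assignment$concentration_uM[treat_pos] <- cmp$concentration_uM
  rownames(assignment) <- NULL

  # programmed shift per compound and feature, in units of the robust SD of
  # DMSO well medians (= site noise scaled by the median-of-n-sites factor)
  k_sites <- median_sd_factor(ns)
  k_reps <- median_sd_factor(np)
  unit <- config$site_noise_sd * k_sites * sigma
  effect <- matrix(0, nrow = nrow(cmp), ncol = nf,
                   dimnames = list(cmp$compound, feats))
  for (i in seq_len(nrow(cmp))) {
    sg <- cmp$signature[i]
    if (!is.na(sg)) {
      sig <- config$signatures[[sg]]
      mult <- signature_multiplier(sig, cmp$concentration_uM[i])
      effect[i, sig$affected_features] <- sig$effect_sizes * mult
    }
  }

  well_effect <- matrix(0, nrow = nw, ncol = nf)
  well_effect[treat_pos, ] <- effect
  toxicity <- rep(1, nw)
  toxicity[treat_pos] <- cmp$toxicity

  tables <- vector("list", np)
  layouts <- vector("list", np)
  shift_step <- if (config$layout_shift) max(1L, nw %/% np) else 0L
  noisy <- feature_class == "noisy"
  for (p in seq_len(np)) {
    # cyclic permutation of the compound assignment across replicates
    perm <- 1L + (seq_len(nw) - 1L + (p - 1L) * shift_step) %% nw
    lay <- assignment[perm, , drop = FALSE]
    plate_id <- sprintf("P%02d", p)
    layouts[[p]] <- data.frame(plate = plate_id, well = wells,
                               compound = lay$compound,
                               concentration_uM = lay$concentration_uM,
                               role = lay$role, stringsAsFactors = FALSE)
    plate_offset <- rnorm(nf, sd = config$plate_offset_sd) * sigma

    base <- sweep(well_effect[perm, , drop = FALSE], 2L, unit, `*`)
    base <- sweep(base, 2L, mu + plate_offset, `+`)
    if (any(noisy)) {
      # irreproducible features: per-(plate, well) noise dominating the scale
      nn <- sum(noisy)
      base[, noisy] <- base[, noisy] +
        matrix(rnorm(nw * nn), nw, nn) %*% diag(3 * sigma[noisy], nn)
    }
    rows <- nw * ns
    x <- base[rep(seq_len(nw), each = ns), , drop = FALSE] +
      matrix(rnorm(rows * nf), rows, nf) *
        rep(config$site_noise_sd * sigma, each = rows)
    colnames(x) <- feats

    cc_mean <- config$baseline_cells_per_site * toxicity[perm]
    cc <- pmax(0, round(rnorm(rows,
                              mean = rep(cc_mean, each = ns),
                              sd = config$cell_count_cv *
                                config$baseline_cells_per_site)))
    tables[[p]] <- feature_table(
      plate_id = plate_id,
      well = rep(wells, each = ns),
      site = rep(seq_len(ns), times = nw),
      cell_count = cc, values = x
    )
  }

  truth_cmp <- data.frame(
    compound = cmp$compound, signature = cmp$signature,
    concentration_uM = cmp$concentration_uM, toxicity = cmp$toxicity,
    active_fraction = rowSums(effect != 0) / nf,
    stringsAsFactors = FALSE
  )
  structure(
    list(tables = tables, layouts = layouts,
         truth = list(compounds = truth_cmp,
                      expected_z = effect / k_reps,
                      feature_class = feature_class,
                      feature_location = mu, feature_scale = sigma),
         config = config),
    class = "cpa_screen"
  )
}

#' Simulate two biological repeats of a reference plate
#'
#' Produces paired well-level profiles whose per-feature between-repeat
#' Pearson correlation is `target_r` in expectation: a shared per-well
#' effect of variance `target_r / (1 - target_r)` (relative to unit repeat
#' noise) models the reference compounds, independent noise the rest. Used
#' to exercise replicate-reproducibility feature selection at a programmed
#' correlation.
#'
#' @param n_wells Number of wells.
#' @param n_features Number of features.
#' @param target_r Expected between-repeat correlation per feature; scalar
#'   or vector of length `n_features`, each in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with elements `repeat1` and `repeat2`, each a
#'   `well_profiles` object (wells double as compound labels).
#' @export
simulate_feature_repeats <- function(n_wells = 96L, n_features = 200L,
                                     target_r = 0.95, seed = 1L) {
  stopifnot(all(target_r >= 0), all(target_r < 1), n_wells >= 3L)
  target_r <- rep_len(target_r, n_features)
  set.seed(seed)
  feats <- default_feature_names(n_features)
  wells <- well_names(if (n_wells <= 24) 24L else if (n_wells <= 96) 96L
                      else if (n_wells <= 384) 384L else 1536L)[seq_len(n_wells)]
  s <- sqrt(target_r / (1 - target_r))
  shared <- matrix(rnorm(n_wells * n_features), n_wells) *
    rep(s, each = n_wells)
  mk <- function() {
    v <- shared + matrix(rnorm(n_wells * n_features), n_wells)
    colnames(v) <- feats
    well_profiles(meta = data.frame(well = wells, compound = wells,
                                    concentration_uM = 10,
                                    role = "treatment",
                                    cell_count = 100,
                                    stringsAsFactors = FALSE),
                  values = v)
  }
  list(repeat1 = mk(), repeat2 = mk())
}

#' Simulate a qPCR Ct table with a programmed fold change
#'
#' Constructs Ct values for one target gene and two reference genes in
#' treatment and control groups such that the expected relative expression
#' (2^-ddCt of treatment vs the control mean) equals `true_fold_change`.
#' Gaussian cycle noise of SD `ct_noise_sd` is added to every Ct.
#'
#' @param n_replicates Biological replicates per group.
#' @param true_fold_change Programmed relative expression (> 0).
#' @param ct_noise_sd Ct noise SD in cycles (>= 0).
#' @param seed Integer seed.
#' @param target_gene,reference_genes Gene labels.
#' @return A `qpcr_table` data frame with columns `sample`, `group`,
#'   `gene`, `replicate`, `ct` and attributes `target_gene`,
#'   `reference_genes`, `control_group`.
#' @export
#' @examples
#' simulate_qpcr(3, true_fold_change = 0.75, ct_noise_sd = 0)
simulate_qpcr <- function(n_replicates, true_fold_change, ct_noise_sd = 0,
                          seed = 1L, target_gene = "NRAS",
                          reference_genes = c("GAPDH", "ACTB")) {
  stopifnot(n_replicates >= 1L, true_fold_change > 0)
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  ref_ct <- seq(19, by = 2, length.out = length(reference_genes))
  target_ct_control <- 24
  genes <- c(target_gene, reference_genes)
  grid <- expand.grid(replicate = seq_len(n_replicates), gene = genes,
                      group = c("control", "treatment"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- ifelse(grid$gene == target_gene,
                 ifelse(grid$group == "treatment",
                        target_ct_control - log2(true_fold_change),
                        target_ct_control),
                 ref_ct[match(grid$gene, reference_genes)])
  out <- data.frame(
    sample = paste0(ifelse(grid$group == "treatment", "T", "C"),
                    grid$replicate),
    group = grid$group, gene = grid$gene, replicate = grid$replicate,
    ct = base + rnorm(nrow(grid), sd = ct_noise_sd),
    stringsAsFactors = FALSE
  )
  structure(out, target_gene = target_gene,
            reference_genes = reference_genes,
            control_group = "control", class = c("qpcr_table", "data.frame"))
}
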