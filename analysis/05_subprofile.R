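#!/usr/bin/env Rscript
# Step 5 — bioactivity-cluster subprofile matching.
#
# Builds a synthetic reference library of 13 bioactivity clusters (each a
# subprofile: the element-wise median of its members' Z-scores over the
# cluster's dominant features), then matches noisy copies of two cluster
# subprofiles and one unrelated random profile against the library at the
# 85% assignment threshold. Writes results/cluster_matches.csv.

suppressPackageStartupMessages(library(cellpaintr))
dir.create("results", showWarnings = FALSE)

lib <- synthetic_cluster_library(n_features = 579, n_dominant = 60,
                                 seed = 303)
write_cluster_library(lib, file.path("results", "cluster_library"))

mkfp <- function(z, name) {
  structure(list(compound = name, concentration_uM = 10,
                 z = setNames(z, sprintf("F%04d", seq_along(z))),
                 induction = induction(z), relative_cell_count = 100,
                 cell_count_class = "normal",
                 regions = cpa_regions(length(z)),
                 excluded = character(0), n_vehicle = 10,
                 scale_method = "mad", change_threshold = 3),
            class = "fingerprint")
}

set.seed(304)
noisy_copy <- function(cluster_name) {
  cl <- lib$clusters[[cluster_name]]
  sub <- build_cluster_subprofile(cl$members, cl$dominant)
  z <- rnorm(579, sd = 0.3)
  z[cl$dominant] <- sub + rnorm(length(sub), sd = 0.2 * sd(sub))
  z
}
queries <- list(
  mkfp(noisy_copy("HSP90"), "HSP90-like"),
  mkfp(noisy_copy("tubulin"), "tubulin-like"),
  mkfp(rnorm(579, sd = 2), "unrelated")
)

rows <- do.call(rbind, lapply(queries, function(q) {
  rep <- match_clusters(q, lib)
  best <- rep[1L, ]
  data.frame(query = q$compound, best_cluster = best$cluster,
             biosimilarity = best$subprofile_biosimilarity,
             assigned = best$assigned,
             assigned_to = paste(attr(rep, "assigned_to"), collapse = ";"))
}))
write.csv(rows, file.path("results", "cluster_matches.csv"),
          row.names = FALSE)
print(rows, row.names = FALSE)
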