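#!/usr/bin/env Rscript
# Step 1 — simulate a cell painting screen with known ground truth.
#
# Builds a 384-well triplicate screen in which two pairs of compounds share
# two disjoint phenotype signatures (pair A: signature S1, pair B: S2) and a
# third signature drives a cytotoxic reference. All remaining wells receive
# inert filler compounds; ~10% of the wells are DMSO vehicle. The per-site
# feature tables and plate layouts are written under results/screen/.

suppressPackageStartupMessages(library(cellpaintr))

out_dir <- file.path("results", "screen")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_features <- 400L
k <- as.integer(0.2 * n_features)   # 20% of features respond per signature

set.seed(101)
signatures <- list(
  phenotype_signature("S1", seq_len(k),
                      sample(c(-5, 5), k, replace = TRUE)),
  phenotype_signature("S2", k + seq_len(k),
                      sample(c(-5, 5), k, replace = TRUE)),
  phenotype_signature("TOX", 2L * k + seq_len(k),
                      sample(c(-6, 6), k, replace = TRUE))
)
compounds <- data.frame(
  compound = c("CPA-A1", "CPA-A2", "CPB-B1", "CPB-B2", "TOXREF"),
  concentration_uM = 10,
  signature = c("S1", "S1", "S2", "S2", "TOX"),
  toxicity = c(1, 1, 1, 1, 0.4)      # TOXREF kills ~60% of the cells
)

cfg <- simulation_config(n_features = n_features, signatures = signatures,
                         compounds = compounds, seed = 101)
scr <- simulate_screen(cfg)

for (p in seq_along(scr$tables)) {
  write_feature_table(scr$tables[[p]],
                      file.path(out_dir, sprintf("plate%02d_features.csv", p)))
  write_plate_layout(scr$layouts[[p]],
                     file.path(out_dir, sprintf("plate%02d_layout.csv", p)))
}
saveRDS(scr$truth, file.path(out_dir, "truth.rds"))
cat("wrote", length(scr$tables), "replicate plates to", out_dir, "\n")
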