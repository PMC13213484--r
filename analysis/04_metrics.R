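#!/usr/bin/env Rscript
# Step 4 — biosimilarity structure and per-fingerprint detail.
#
# Re-runs the pipeline on the simulated screen and inspects the recovered
# structure: within-pair vs between-pair biosimilarity, region summaries
# and the most strongly changed features of the reference compounds.
# Writes results/biosimilarity_pairs.csv and results/top_changed.csv and,
# if the run produced a cross-biosimilarity matrix, a heatmap.

suppressPackageStartupMessages({
  library(cellpaintr)
  library(ggplot2)
})

in_dir <- file.path("results", "screen")
plates <- sort(list.files(in_dir, pattern = "^plate\\d+_features\\.csv$"))
if (!length(plates)) stop("run analysis/01_simulate.R first")
tables <- lapply(file.path(in_dir, plates), read_feature_table)
layouts <- lapply(file.path(in_dir, sub("features", "layout", plates)),
                  read_plate_layout)
run <- run_screen_pipeline(tables, layouts)
f <- run$fingerprints

pairs <- data.frame(
  a = c("CPA-A1@10", "CPB-B1@10", "CPA-A1@10", "CPA-A2@10"),
  b = c("CPA-A2@10", "CPB-B2@10", "CPB-B1@10", "CPB-B2@10"),
  relation = c("same signature", "same signature",
               "disjoint signatures", "disjoint signatures")
)
pairs$biosimilarity <- mapply(function(a, b) biosimilarity(f[[a]], f[[b]]),
                              pairs$a, pairs$b)
write.csv(pairs, file.path("results", "biosimilarity_pairs.csv"),
          row.names = FALSE)
print(pairs, row.names = FALSE)

tc <- do.call(rbind, lapply(c("CPA-A1@10", "CPB-B1@10", "TOXREF@10"),
  function(nm) {
    out <- top_changed(f[[nm]], min_abs = 5)
    if (nrow(out)) cbind(profile = nm, utils::head(out, 10)) else NULL
  }))
write.csv(tc, file.path("results", "top_changed.csv"), row.names = FALSE)

for (nm in c("CPA-A1@10", "TOXREF@10")) {
  cat("\nregion summary for", nm, "\n")
  print(region_summary(f[[nm]]), row.names = FALSE)
}

if (!is.null(run$cross_biosimilarity)) {
  p <- plot_biosimilarity_matrix(run$cross_biosimilarity)
  ggsave(file.path("results", "cross_biosimilarity.png"), p,
         width = 6, height = 5, dpi = 150)
}
p <- plot_fingerprint_heatmap(f[grepl("^(CPA|CPB|TOXREF)", names(f))])
ggsave(file.path("results", "fingerprints.png"), p,
       width = 9, height = 3.5, dpi = 150)
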