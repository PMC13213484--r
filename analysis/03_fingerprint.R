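#!/usr/bin/env Rscript
# Step 3 — aggregate, fingerprint and summarise the simulated screen.
#
# Reads the per-site feature tables written by 01_simulate.R, aggregates
# sites to well medians and replicates to compound-level profiles, computes
# robust Z-score fingerprints against the DMSO vehicle wells and writes the
# full run (fingerprints, induction/activity summary, cross-biosimilarity,
# region summaries, resolved parameters) to results/run/.

suppressPackageStartupMessages(library(cellpaintr))

in_dir <- file.path("results", "screen")
plates <- sort(list.files(in_dir, pattern = "^plate\\d+_features\\.csv$"))
if (!length(plates)) stop("run analysis/01_simulate.R first")

tables <- lapply(file.path(in_dir, plates), read_feature_table)
layouts <- lapply(file.path(in_dir, sub("features", "layout", plates)),
                  read_plate_layout)

run <- run_screen_pipeline(tables, layouts,
                           out_dir = file.path("results", "run"))
print(run)

# Compounds of interest, with their induction and activity calls
keep <- grepl("^(CPA|CPB|TOXREF)", run$summary$compound)
print(run$summary[keep, ], row.names = FALSE)
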