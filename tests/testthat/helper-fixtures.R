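# Shared fixture builders: everything is generated in code, no data files.

# well_profiles from a plain matrix; compound labels default to well names
make_profiles <- function(values, compound = NULL, role = "treatment",
                          concentration = 10, cell_count = 100) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("F%04d", seq_len(ncol(values)))
  }
  wells <- well_names(96)[seq_len(nrow(values))]
  well_profiles(
    meta = data.frame(well = wells,
                      compound = compound %||% wells,
                      concentration_uM = concentration,
                      role = rep_len(role, nrow(values)),
                      cell_count = rep_len(cell_count, nrow(values)),
                      stringsAsFactors = FALSE),
    values = values
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Pearson correlation from raw sums, for oracle checks
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# two vectors with an exact Pearson correlation r, n points
vectors_with_correlation <- function(r, n = 20L, seed = 1L) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1L]
  e <- scale(stats::residuals(stats::lm(rnorm(n) ~ x)))[, 1L]
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# small signature-recovery screen used by several tests
make_signature_screen <- function(seed, n_features = 120L, n_wells = 96L,
                                  effect = 5, fraction = 0.2) {
  k <- round(fraction * n_features)
  set.seed(seed + 90000L)
  sigs <- list(
    phenotype_signature("sigA", seq_len(k),
                        sample(c(-effect, effect), k, replace = TRUE)),
    phenotype_signature("sigB", k + seq_len(k),
                        sample(c(-effect, effect), k, replace = TRUE))
  )
  cmp <- data.frame(compound = c("A1", "A2", "B1"),
                    concentration_uM = 10,
                    signature = c("sigA", "sigA", "sigB"),
                    toxicity = 1)
  simulate_screen(simulation_config(
    n_features = n_features, n_wells = n_wells, sites_per_well = 9L,
    vehicle_fraction = 0.25, signatures = sigs, compounds = cmp,
    seed = seed
  ))
}
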