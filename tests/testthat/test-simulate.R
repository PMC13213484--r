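test_that("simulation is deterministic for a fixed seed", {
  cfg <- simulation_config(n_features = 30, n_wells = 24, sites_per_well = 3,
                           vehicle_fraction = 0.25, seed = 11)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)
  expect_false(identical(
    a$tables[[1]]$values,
    simulate_screen(simulation_config(n_features = 30, n_wells = 24,
                                      sites_per_well = 3,
                                      vehicle_fraction = 0.25,
                                      seed = 12))$tables[[1]]$values
  ))
})

test_that("screen structure matches the configuration", {
  cfg <- simulation_config(n_features = 25, n_wells = 96, sites_per_well = 4,
                           n_replicate_plates = 3, vehicle_fraction = 0.2,
                           seed = 3)
  scr <- simulate_screen(cfg)
  expect_length(scr$tables, 3)
  expect_length(scr$layouts, 3)
  for (p in 1:3) {
    tab <- scr$tables[[p]]
    expect_equal(nrow(tab$values), 96 * 4)
    expect_equal(ncol(tab$values), 25)
    expect_setequal(unique(tab$well), well_names(96))
    lay <- scr$layouts[[p]]
    expect_equal(sum(lay$role == "vehicle"), round(0.2 * 96))
    # layout shift is a permutation: every compound exactly once per plate
    expect_false(anyDuplicated(lay$compound) > 0)
    expect_setequal(lay$compound, scr$layouts[[1]]$compound)
  }
  # shifted layouts place compounds at different wells across replicates
  expect_false(identical(scr$layouts[[1]]$compound,
                         scr$layouts[[2]]$compound))
})

test_that("vehicle wells never carry signature effects", {
  sig <- phenotype_signature("s", 1:5, 8)
  cmp <- data.frame(compound = "X", concentration_uM = 10, signature = "s",
                    toxicity = 1)
  scr <- simulate_screen(simulation_config(
    n_features = 20, n_wells = 24, sites_per_well = 3,
    vehicle_fraction = 0.25, signatures = list(sig), compounds = cmp,
    seed = 5))
  tr <- scr$truth
  expect_true(all(tr$expected_z["X", 1:5] != 0))
  filler <- setdiff(rownames(tr$expected_z), "X")
  expect_true(all(tr$expected_z[filler, ] == 0))
  # vehicle wells are not in the compound truth at all
  expect_false(any(grepl("^DMSO", tr$compounds$compound)))
  expect_true(all(grepl("^DMSO", scr$layouts[[1]]$compound[
    scr$layouts[[1]]$role == "vehicle"])))
})

test_that("signature indices beyond the feature space are a configuration error", {
  sig <- phenotype_signature("s", c(1, 50), 2)
  expect_error(
    simulation_config(n_features = 20, n_wells = 24, sites_per_well = 3,
                      signatures = list(sig)),
    "beyond n_features"
  )
})

test_that("zero noise and zero effects give identical wells within a plate", {
  cfg <- simulation_config(n_features = 10, n_wells = 24, sites_per_well = 3,
                           vehicle_fraction = 0.25, site_noise_sd = 0,
                           plate_offset_sd = 0, cell_count_cv = 0, seed = 2)
  scr <- simulate_screen(cfg)
  v <- scr$tables[[1]]$values
  expect_true(all(apply(v, 2, function(col) length(unique(col)) == 1)))
})

test_that("null wells are exchangeable with vehicle wells", {
  # all effects zero: treated and vehicle well medians share a distribution
  cfg <- simulation_config(n_features = 40, n_wells = 96, sites_per_well = 5,
                           vehicle_fraction = 0.5, plate_offset_sd = 0,
                           seed = 9)
  scr <- simulate_screen(cfg)
  prof <- aggregate_sites(scr$tables[[1]], scr$layouts[[1]])
  veh <- prof$values[prof$meta$role == "vehicle", 1]
  trt <- prof$values[prof$meta$role == "treatment", 1]
  expect_gt(stats::ks.test(veh, trt)$p.value, 0.001)
})

test_that("reference-repeat generator hits the programmed correlation", {
  reps <- simulate_feature_repeats(n_wells = 200, n_features = 150,
                                   target_r = 0.9, seed = 4)
  r <- vapply(seq_len(150), function(j) {
    cor(reps$repeat1$values[, j], reps$repeat2$values[, j])
  }, numeric(1))
  expect_equal(mean(r), 0.9, tolerance = 0.02)
})

test_that("qPCR simulation encodes the programmed fold change", {
  tb <- simulate_qpcr(3, true_fold_change = 0.75, ct_noise_sd = 0, seed = 1)
  res <- analyze_qpcr(tb)
  expect_equal(res$delta_ct$rel_expression[res$delta_ct$group == "treatment"],
               rep(0.75, 3))
  tb1 <- simulate_qpcr(4, true_fold_change = 1, ct_noise_sd = 0, seed = 1)
  expect_equal(analyze_qpcr(tb1)$delta_ct$rel_expression, rep(1, 8))
  expect_error(simulate_qpcr(3, 0.5, ct_noise_sd = -1), ">= 0")
})

test_that("noisy qPCR fold-change estimation is unbiased in log space", {
  # closed form: ddCt noise is mean-zero Gaussian, so E[log2 estimate] = log2(fc)
  est <- vapply(1:300, function(s) {
    tb <- simulate_qpcr(3, true_fold_change = 0.75, ct_noise_sd = 0.2,
                        seed = s)
    res <- analyze_qpcr(tb)
    res$summary$geo_mean[res$summary$group == "treatment"]
  }, numeric(1))
  mc_se <- sd(log2(est)) / sqrt(length(est))
  expect_lt(abs(mean(log2(est)) - log2(0.75)), 4 * mc_se + 1e-12)
})
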