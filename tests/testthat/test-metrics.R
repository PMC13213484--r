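test_that("biosimilarity equals clipped Pearson r in percent", {
  expect_equal(biosimilarity(c(1, 2, 3, 4), c(1, 2, 3, 4)), 100)
  expect_equal(biosimilarity(c(1, 2, 3, 4), -c(1, 2, 3, 4)), 0)
  # hand oracle: r = 6.5 / sqrt(5 * 8.75)
  expect_equal(biosimilarity(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               100 * 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_equal(biosimilarity(c(1, 2, 3, 4), c(1, 2, 3, 5)), 98.27,
               tolerance = 1e-4)
})

test_that("biosimilarity matches a brute-force oracle on exhaustive integer vectors", {
  # all length-3 vectors over {-1,0,1}, non-constant, all pairs
  grid <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  grid <- grid[apply(grid, 1, function(v) length(unique(v)) > 1), ]
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      expected <- 100 * max(0, pearson_oracle(grid[i, ], grid[j, ]))
      expect_equal(biosimilarity(grid[i, ], grid[j, ]), expected,
                   tolerance = 1e-9)
    }
  }
})

test_that("biosimilarity is symmetric and invariant under positive affine maps", {
  set.seed(1)
  for (k in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(biosimilarity(a, b), biosimilarity(b, a))
    expect_equal(biosimilarity(3.2 * a + 7, b), biosimilarity(a, b),
                 tolerance = 1e-9)
  }
  expect_warning(out <- biosimilarity(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(out))
  expect_error(biosimilarity(1:4, 1:5), "length")
})

test_that("induction is the exact percent of changed features", {
  z <- rep(0, 579)
  z[seq_len(58)] <- c(rep(4, 29), rep(-4, 29))
  expect_equal(induction(z), 100 * 58 / 579)
  expect_equal(induction(rep(0, 100)), 0)
  expect_equal(induction(rep(10, 7)), 100)
  expect_error(induction(numeric(0)), "empty")
  # invariant to feature order, non-increasing in the threshold
  set.seed(2)
  zz <- rnorm(200, sd = 2)
  expect_equal(induction(zz), induction(sample(zz)))
  thr <- seq(0, 6, by = 0.5)
  vals <- vapply(thr, function(t) induction(zz, t), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("activity call is strict at 5 percent", {
  expect_false(is_active(4.9))
  expect_false(is_active(5.0))
  expect_true(is_active(5.0001))
  expect_true(is_active(13))
})

test_that("cross-biosimilarity filters by induction and stays symmetric", {
  mkfp <- function(z, ind, name) {
    structure(list(compound = name, concentration_uM = 10,
                   z = setNames(z, sprintf("F%04d", seq_along(z))),
                   induction = ind, relative_cell_count = 100,
                   cell_count_class = "normal",
                   regions = cpa_regions(length(z)), excluded = character(0),
                   n_vehicle = 10, scale_method = "mad",
                   change_threshold = 3),
              class = "fingerprint")
  }
  set.seed(3)
  base <- rnorm(30)
  fps <- list(mkfp(base, 50, "a"), mkfp(base, 45, "b"),
              mkfp(rnorm(30), 20, "c"))
  m <- cross_biosimilarity(fps, min_induction = 30)
  expect_equal(dim(m), c(2L, 2L))  # the 20% profile is filtered out
  expect_equal(unname(diag(m)), c(100, 100))
  expect_equal(m[1, 2], 100)      # identical z vectors
  expect_equal(unclass(m), t(unclass(m)))
  expect_error(cross_biosimilarity(fps, min_induction = 48), "induction > 48")
})

test_that("region summary equals brute-force per-block statistics", {
  set.seed(4)
  n <- 60
  z <- rnorm(n, sd = 3)
  fp <- structure(list(compound = "x", concentration_uM = 10,
                       z = setNames(z, sprintf("F%04d", 1:n)),
                       induction = induction(z), relative_cell_count = 100,
                       cell_count_class = "normal",
                       regions = cpa_regions(n), excluded = character(0),
                       n_vehicle = 10, scale_method = "mad",
                       change_threshold = 3),
                  class = "fingerprint")
  rs <- region_summary(fp)
  for (r in c("cell", "cytoplasm", "nuclei")) {
    idx <- fp$regions[[r]]
    expect_equal(rs$mean_abs_z[rs$region == r], mean(abs(z[idx])))
    expect_equal(rs$n_changed[rs$region == r], sum(abs(z[idx]) >= 3))
  }
  # zero fingerprint -> all means zero
  fp0 <- fp; fp0$z[] <- 0
  expect_equal(region_summary(fp0)$mean_abs_z, rep(0, 3))
  # block-localised signal lands in its own region only
  fp2 <- fp; fp2$z[] <- 0; fp2$z[fp$regions$cytoplasm] <- 2
  rs2 <- region_summary(fp2)
  expect_equal(rs2$mean_abs_z, c(0, 2, 0))
})

test_that("the canonical 579-feature partition has the published block sizes", {
  reg <- cpa_regions(579)
  expect_equal(range(reg$cell), c(1, 229))
  expect_equal(range(reg$cytoplasm), c(230, 461))
  expect_equal(range(reg$nuclei), c(462, 579))
  # partition property over assorted lengths
  for (n in c(3, 10, 57, 579, 1716)) {
    reg <- cpa_regions(n)
    expect_equal(sort(unlist(reg, use.names = FALSE)), seq_len(n))
  }
})

test_that("top_changed orders by |z| with index tie-breaks", {
  z <- c(0.5, 12.25, -11.20, 3, 10, -10)
  names(z) <- sprintf("F%04d", seq_along(z))
  out <- top_changed(z, min_abs = 10)
  expect_equal(out$z, c(12.25, -11.20, 10, -10))
  expect_equal(out$feature_index, c(2L, 3L, 5L, 6L))  # tie 10 vs -10 by index
  expect_equal(nrow(top_changed(rep(0, 5), 10)), 0)
  expect_equal(nrow(top_changed(c(9.9, -9.5), 10)), 0)
})
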