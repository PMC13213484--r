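test_that("site aggregation takes per-feature medians within each well", {
  # 2 wells x 9 sites, one feature constant, one a 1..9 ramp
  vals <- cbind(F0001 = rep(7, 18),
                F0002 = c(1:9, 11:19))
  tab <- feature_table("P01", well = rep(c("A01", "A02"), each = 9),
                       site = rep(1:9, 2), cell_count = rep(10, 18),
                       values = vals)
  prof <- aggregate_sites(tab)
  expect_equal(prof$meta$well, c("A01", "A02"))
  expect_equal(unname(prof$values[, "F0001"]), c(7, 7))
  expect_equal(unname(prof$values[, "F0002"]), c(5, 15))  # sort-and-pick
  expect_equal(prof$meta$cell_count, c(10, 10))
})

test_that("missing site values are ignored and all-missing wells flagged", {
  vals <- cbind(F0001 = c(NA, 2:9), F0002 = rep(NA_real_, 9))
  tab <- feature_table("P01", well = rep("A01", 9), site = 1:9,
                       cell_count = rep(5, 9), values = vals)
  prof <- aggregate_sites(tab)
  expect_equal(unname(prof$values[1, "F0001"]), median(2:9))
  expect_true(is.na(prof$values[1, "F0002"]))
  qc <- attr(prof, "qc")
  expect_equal(qc$feature, "F0002")
})

test_that("replicate aggregation matches compounds by label, not position", {
  set.seed(1)
  base <- matrix(rnorm(5 * 4), 5, 4,
                 dimnames = list(NULL, sprintf("F%04d", 1:4)))
  p1 <- make_profiles(base, compound = paste0("c", 1:5))
  # same values, rows shuffled with compound labels attached
  shuffle <- c(3, 1, 5, 2, 4)
  p2 <- make_profiles(base[shuffle, ], compound = paste0("c", 1:5)[shuffle])
  agg_shift <- aggregate_replicates(list(p1, p2))
  agg_plain <- aggregate_replicates(list(p1, p1))
  expect_equal(agg_shift$values, agg_plain$values)
  expect_equal(agg_shift$meta$compound, paste0("c", 1:5))
})

test_that("replicate aggregation is an element-wise median across plates", {
  mk <- function(v) make_profiles(matrix(v, 1, 1,
                                         dimnames = list(NULL, "F0001")),
                                  compound = "c1")
  agg <- aggregate_replicates(list(mk(1), mk(2), mk(10)))
  expect_equal(unname(agg$values[1, 1]), 2)
  # permutation-invariant in plate order
  agg2 <- aggregate_replicates(list(mk(10), mk(1), mk(2)))
  expect_equal(agg, agg2)
  # identical plates reduce to a single plate
  one <- make_profiles(matrix(rnorm(8), 2, 4), compound = c("a", "b"))
  expect_equal(aggregate_replicates(list(one, one, one))$values, one$values)
})

test_that("a compound missing from one plate aggregates with a warning", {
  p1 <- make_profiles(matrix(1:4, 2, 2), compound = c("a", "b"))
  p2 <- make_profiles(matrix(5:6, 1, 2), compound = "a")
  expect_warning(agg <- aggregate_replicates(list(p1, p2)), "absent")
  expect_equal(nrow(agg$values), 2)
  expect_equal(unname(agg$values[agg$meta$compound == "b", 1]), 2)
})

test_that("fingerprint Z-scores match the hand-computed robust Z", {
  veh <- make_profiles(matrix(c(1, 2, 3, 4, 5), 5, 1,
                              dimnames = list(NULL, "F0001")),
                       role = "vehicle")
  # need >= 3 features for regions; replicate the feature thrice
  veh3 <- make_profiles(matrix(c(1:5, 1:5, 1:5), 5, 3), role = "vehicle")
  trt <- make_profiles(matrix(c(6, 6, 6), 1, 3), compound = "cpd")
  fp <- fingerprint(trt, veh3)
  # median 3, MAD 1, robust scale 1.4826 -> z = 3 / 1.4826
  expect_equal(unname(fp$z), rep(3 / 1.4826, 3), tolerance = 1e-12)
  expect_equal(fp$compound, "cpd")
})

test_that("the fingerprint of the vehicle median vector is exactly zero", {
  set.seed(2)
  veh <- make_profiles(matrix(rnorm(7 * 5), 7, 5), role = "vehicle")
  med <- apply(veh$values, 2, median)
  trt <- make_profiles(matrix(med, 1, 5), compound = "null")
  fp <- fingerprint(trt, veh)
  expect_equal(unname(fp$z), rep(0, 5))
  expect_equal(fp$induction, 0)
})

test_that("Z-scoring is equivariant under positive feature rescaling", {
  set.seed(3)
  veh <- make_profiles(matrix(rnorm(9 * 4), 9, 4), role = "vehicle")
  trt <- make_profiles(matrix(rnorm(4, sd = 3), 1, 4), compound = "x")
  fp1 <- fingerprint(trt, veh)
  scal <- c(10, 0.2, 7, 100)
  veh2 <- make_profiles(sweep(veh$values, 2, scal, `*`), role = "vehicle")
  trt2 <- make_profiles(sweep(trt$values, 2, scal, `*`), compound = "x")
  fp2 <- fingerprint(trt2, veh2)
  expect_equal(fp1$z, fp2$z, tolerance = 1e-10)
})

test_that("zero-dispersion features are excluded, not infinite", {
  veh_vals <- cbind(F0001 = rep(4, 5), F0002 = 1:5, F0003 = c(2, 4, 6, 8, 10),
                    F0004 = 5:9)
  veh <- make_profiles(veh_vals, role = "vehicle")
  trt <- make_profiles(matrix(c(9, 3, 6, 7), 1, 4), compound = "x")
  fp <- fingerprint(trt, veh)
  expect_equal(fp$excluded, "F0001")
  expect_length(fp$z, 3)
  expect_true(all(is.finite(fp$z)))
})

test_that("a vehicle profile scored as test has near-zero induction", {
  set.seed(4)
  veh <- make_profiles(matrix(rnorm(20 * 50), 20, 50), role = "vehicle")
  self <- veh[1, ]
  self$meta$role <- "treatment"
  fp <- fingerprint(self, veh)
  expect_lt(fp$induction, 5)
})

test_that("relative cell count bands follow the 80/50 boundaries", {
  veh <- make_profiles(matrix(rnorm(3 * 3), 3, 3), role = "vehicle",
                       cell_count = 100)
  mk <- function(cc) make_profiles(matrix(rnorm(3), 1, 3), compound = "x",
                                   cell_count = cc)
  same <- relative_cell_count(mk(100), veh)
  expect_equal(same$percent, 100)
  expect_equal(same$class, "normal")
  arrest <- relative_cell_count(mk(40), veh)
  expect_equal(arrest$percent, 40)
  expect_equal(arrest$class, "growth_arrest")
  ok <- relative_cell_count(mk(84), veh)
  expect_equal(ok$percent, 84)
  expect_equal(ok$class, "normal")
  expect_equal(relative_cell_count(mk(79.9), veh)$class, "reduced")
  veh0 <- make_profiles(matrix(rnorm(9), 3, 3), role = "vehicle",
                        cell_count = 0)
  expect_error(relative_cell_count(mk(50), veh0), "positive")
})

test_that("fingerprint requires at least three vehicle profiles", {
  veh <- make_profiles(matrix(rnorm(2 * 4), 2, 4), role = "vehicle")
  trt <- make_profiles(matrix(rnorm(4), 1, 4), compound = "x")
  expect_error(fingerprint(trt, veh), "3 vehicle")
})
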