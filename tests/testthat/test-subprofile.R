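mk_fp <- function(z, name = "x", regions = NULL) {
  structure(list(compound = name, concentration_uM = 10,
                 z = setNames(z, sprintf("F%04d", seq_along(z))),
                 induction = induction(z), relative_cell_count = 100,
                 cell_count_class = "normal",
                 regions = regions %||% cpa_regions(length(z)),
                 excluded = character(0), n_vehicle = 10,
                 scale_method = "mad", change_threshold = 3),
            class = "fingerprint")
}

test_that("cluster subprofile is the member median on dominant features", {
  m <- rbind(c(1, 5, 2, 8), c(3, 5, 0, 9), c(2, 5, 7, 1))
  colnames(m) <- sprintf("F%04d", 1:4)
  sub <- build_cluster_subprofile(m, c(1, 3, 4))
  # sort-based oracle per column
  expect_equal(unname(sub), c(2, 2, 8))
  expect_equal(names(sub), c("F0001", "F0003", "F0004"))
  # single member: its own restricted vector
  expect_equal(unname(build_cluster_subprofile(m[1, , drop = FALSE], 2:3)),
               c(5, 2))
  # mirrored members cancel to a zero subprofile
  z <- c(4, -2, 7)
  mm <- rbind(z, -z); colnames(mm) <- sprintf("F%04d", 1:3)
  expect_equal(unname(build_cluster_subprofile(mm, 1:3)), c(0, 0, 0))
  expect_error(build_cluster_subprofile(m, integer(0)), "empty")
  expect_error(build_cluster_subprofile(m, 9), "out of range")
})

test_that("a fingerprint equal to a subprofile is assigned at 100%", {
  lib <- synthetic_cluster_library(n_features = 120, n_dominant = 25,
                                   seed = 2)
  cl <- lib$clusters[["HDAC"]]
  sub <- build_cluster_subprofile(cl$members, cl$dominant)
  set.seed(21)
  z <- rnorm(120, sd = 0.1)
  z[cl$dominant] <- sub
  report <- match_clusters(mk_fp(z), lib)
  hd <- report[report$cluster == "HDAC", ]
  expect_equal(hd$subprofile_biosimilarity, 100)
  expect_true(hd$assigned)
  expect_equal(attr(report, "assigned_to"), "HDAC")
})

test_that("a fingerprint orthogonal to every subprofile is never assigned", {
  set.seed(3)
  lib <- synthetic_cluster_library(n_features = 150, n_dominant = 30,
                                   seed = 4)
  # build the constraint matrix: r(fp[dom], sub) = 0 is linear in fp
  w <- t(vapply(lib$clusters, function(cl) {
    sub <- build_cluster_subprofile(cl$members, cl$dominant)
    row <- numeric(150)
    row[cl$dominant] <- sub - mean(sub)
    row
  }, numeric(150)))
  v <- rnorm(150)
  v <- v - t(w) %*% solve(w %*% t(w), w %*% v)  # project onto null space
  report <- match_clusters(mk_fp(as.numeric(v)), lib)
  expect_equal(report$subprofile_biosimilarity, rep(0, 13), tolerance = 1e-8)
  expect_false(any(report$assigned))
  expect_length(attr(report, "assigned_to"), 0)
})

test_that("assignment is monotone in the threshold", {
  lib <- synthetic_cluster_library(n_features = 100, n_dominant = 20,
                                   seed = 5)
  cl <- lib$clusters[["tubulin"]]
  sub <- build_cluster_subprofile(cl$members, cl$dominant)
  set.seed(6)
  z <- rnorm(100, sd = 1)
  z[cl$dominant] <- sub + rnorm(20, sd = 0.5 * sd(sub))
  fp <- mk_fp(z)
  thresholds <- c(99, 95, 85, 70, 50, 20)
  n_assigned <- vapply(thresholds, function(t) {
    sum(match_clusters(fp, lib, assign_threshold = t)$assigned)
  }, numeric(1))
  expect_true(all(diff(n_assigned) >= 0))
})

test_that("feature-space mismatch is an error", {
  lib <- synthetic_cluster_library(n_features = 80, seed = 7)
  expect_error(match_clusters(mk_fp(rnorm(50)), lib), "feature space")
})

test_that("noisy copies of a subprofile are assigned reliably", {
  lib <- synthetic_cluster_library(n_features = 200, n_dominant = 40,
                                   seed = 8)
  cl <- lib$clusters[["BET"]]
  sub <- build_cluster_subprofile(cl$members, cl$dominant)
  set.seed(9)
  hits <- vapply(1:30, function(i) {
    z <- rnorm(200, sd = 0.3)
    z[cl$dominant] <- sub + rnorm(40, sd = 0.2 * sd(sub))
    report <- match_clusters(mk_fp(z), lib)
    identical(attr(report, "assigned_to"), "BET")
  }, logical(1))
  expect_true(all(hits))
})

test_that("the synthetic library carries the 13 canonical cluster names", {
  lib <- synthetic_cluster_library(n_features = 60, seed = 1)
  expect_length(lib$clusters, 13)
  expect_true(all(c("AKT_PI3K_MTOR", "HDAC", "HSP90", "tubulin",
                    "uncoupler") %in% names(lib$clusters)))
  for (cl in lib$clusters) {
    expect_gte(nrow(cl$members), 1)
    expect_true(all(cl$dominant >= 1 & cl$dominant <= 60))
  }
})
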