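# Chain ratios, PCA, group comparisons, richness.

toy_matrix <- function() {
  m <- matrix(c(10, 5, 20, 10, 8, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"),
                              c("CL(78:12)", "CL(72:8)")))
  class(m) <- c("profile_matrix", class(m))
  m
}

test_that("chain ratio divides long by short and is scale-invariant per
           patient", {
  m <- toy_matrix()
  r <- chain_ratio(m)
  expect_equal(as.numeric(r), c(2, 2, 4))
  m2 <- m; m2["p1", ] <- m2["p1", ] * 7.5
  expect_equal(as.numeric(chain_ratio(m2)), c(2, 2, 4))
  expect_error(chain_ratio(m, long_species = "CL(80:14)"), "missing species")
  m3 <- m; m3["p2", "CL(72:8)"] <- 0
  r3 <- chain_ratio(m3)
  expect_identical(attr(r3, "n_excluded"), 1L)
  expect_identical(names(r3), c("p1", "p3"))
})

test_that("log-centered PCA has unit-sum contributions and ordered
           variance", {
  set.seed(9)
  m <- matrix(abs(rnorm(80, 20, 5)), 8, 10,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:10)))
  pc <- log_center_pca(m)
  expect_equal(unname(colSums(pc$contributions)), rep(100, ncol(pc$scores)),
               tolerance = 1e-9)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_true(all(pc$explained >= 0 & pc$explained <= 1))
  expect_error(log_center_pca(matrix(3, 4, 4)), "constant")
})

test_that("PCA scores are invariant to per-species constant shifts on the
           log scale", {
  set.seed(10)
  m <- matrix(abs(rnorm(60, 20, 5)), 6, 10,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:10)))
  shift <- runif(10, -0.5, 0.5)
  m2 <- sweep(log10(m + 1), 2, shift, "+")
  m2 <- 10^m2 - 1  # so log10(m2 + 1) = log10(m + 1) + shift
  pc1 <- log_center_pca(m)
  pc2 <- log_center_pca(m2)
  expect_equal(abs(pc1$scores), abs(pc2$scores), tolerance = 1e-8)
})

test_that("disjoint class profiles separate completely on PC1", {
  set.seed(11)
  a <- matrix(abs(rnorm(50, 100, 5)), 5, 10)
  b <- matrix(abs(rnorm(50, 5, 1)), 5, 10)
  b[, 1:5] <- abs(rnorm(25, 300, 10))
  m <- rbind(a, b)
  dimnames(m) <- list(paste0("p", 1:10), paste0("s", 1:10))
  pc <- log_center_pca(m)
  s1 <- pc$scores[1:5, 1]; s2 <- pc$scores[6:10, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("duplicating every patient row leaves loadings unchanged", {
  set.seed(12)
  m <- matrix(abs(rnorm(60, 20, 5)), 6, 10,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:10)))
  m2 <- rbind(m, m)
  rownames(m2) <- paste0("q", 1:12)
  l1 <- log_center_pca(m)$loadings
  l2 <- log_center_pca(m2)$loadings
  expect_equal(abs(l1), abs(l2), tolerance = 1e-8)
})

test_that("group comparisons gate on normality, adjust with Holm, and guard
           group sizes", {
  set.seed(13)
  x <- c(rnorm(20), rnorm(20, 5))
  g <- rep(c("a", "b"), each = 20)
  res <- gc <- group_compare(x, g)
  expect_lt(res$p_adj, 0.001)
  # a single comparison: Holm equals the raw p
  expect_identical(res$p, res$p_adj)
  # identical groups: non-significant, adjusted >= raw
  same <- group_compare(rep(c(1, 2, 3, 4, 5), 2), rep(c("a", "b"), each = 5))
  expect_gte(same$p_adj, same$p)
  expect_gt(same$p_adj, 0.5)
  # clearly non-normal data selects the rank test
  y <- c(rexp(15)^3, rexp(15)^3 + 50)
  res2 <- group_compare(y, rep(c("a", "b"), each = 15))
  expect_identical(res2$method, "wilcoxon")
  expect_error(group_compare(c(1, 2, 1, 2, 3, 4), c("a", "a", "b", "b", "b", "b")),
               "a")
  # Holm monotonicity over multiple comparisons
  set.seed(14)
  z <- c(rnorm(10), rnorm(10, 0.5), rnorm(10, 3))
  gz <- rep(c("g1", "g2", "g3"), each = 10)
  r3 <- group_compare(z, gz)
  ord <- order(r3$p)
  expect_true(all(diff(r3$p_adj[ord]) >= -1e-12))
  expect_true(all(r3$p_adj >= r3$p))
})

test_that("species richness counts thresholded detections", {
  m <- matrix(c(5, 2, 0, 9, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  expect_equal(unname(species_richness(m, threshold = 3)), c(1, 1))
  expect_equal(unname(species_richness(m, threshold = Inf)), c(0, 0))
  expect_equal(unname(species_richness(matrix(0, 1, 3,
    dimnames = list("p", c("a", "b", "c"))))), 0)
})

test_that("cohorts calibrated to the published class ratios recover them", {
  # smaller companion cohorts to the main normal/grade-2 recovery runs:
  # grade 1 astrocytoma, and glioblastoma where the long-chain species is
  # absent so the recovered ratio sits at the noise floor
  cfg <- cl_default_config()
  cfg$cohort$patient_rows <- 3; cfg$cohort$patient_cols <- 3
  pm1 <- profile_cohort("AST1", n_patients = 8, config = cfg, seed = 301)
  r1 <- chain_ratio(pm1)
  se1 <- sd(r1) / sqrt(length(r1))
  expect_lt(abs(mean(r1) - 0.05), 3 * se1 + 0.005)
  pm4 <- profile_cohort("GBM", n_patients = 6, config = cfg, seed = 304)
  r4 <- chain_ratio(pm4)
  expect_lte(mean(r4), 0.02)
})
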