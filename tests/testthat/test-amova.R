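test_that("pairwise distances count differing loci", {
  m <- marker_matrix(rbind(a = c(1L, 0L, 1L), b = c(1L, 1L, 0L),
                           c = c(0L, 1L, 0L)))
  d <- pairwise_distance(m)
  expect_equal(d["a", "b"], 2)
  expect_equal(d["b", "c"], 1)
  expect_equal(d["a", "c"], 3)  # complementary rows over 3 loci
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
})

test_that("one-way AMOVA reproduces the hand-computed toy decomposition", {
  m <- marker_matrix(rbind(a = c(1L, 0L), b = c(1L, 1L),
                           c = c(0L, 0L), e = c(0L, 1L)))
  d <- pairwise_distance(m)
  res <- amova_oneway(d, c("g1", "g1", "g2", "g2"), n_perm = 0)
  expect_equal(res$levels$SS, c(1, 1))  # SS_among, SS_within (total 2)
  expect_equal(res$levels$sigma, c(0.25, 0.5))
  expect_equal(res$phi_st, 1 / 3)
  expect_equal(sum(res$levels$pct_total), 100)

  # internally identical, mutually fixed groups -> phi = 1
  m2 <- marker_matrix(rbind(a = c(1L, 1L), b = c(1L, 1L),
                            c = c(0L, 0L), e = c(0L, 0L)))
  res2 <- amova_oneway(pairwise_distance(m2), c("x", "x", "y", "y"),
                       n_perm = 0)
  expect_equal(res2$phi_st, 1)

  expect_error(amova_oneway(d, c("g1", "g1", "g1", "g2"), n_perm = 0),
               "singleton")
})

test_that("variance components reconstruct the observed mean squares", {
  for (seed in 1:4) {
    v <- random_binary_matrix(18, 10, seed + 40)
    groups <- rep(c("A", "B", "C"), times = c(5, 6, 7))
    d <- pairwise_distance(marker_matrix(v))
    res <- amova_oneway(d, groups, n_perm = 0)
    N <- 18; G <- 3
    n0 <- (N - sum(c(5, 6, 7)^2) / N) / (G - 1)
    ms <- res$levels$SS / res$levels$df
    expect_equal(res$levels$sigma[2], ms[2])
    expect_equal(res$levels$sigma[1] * n0 + res$levels$sigma[2], ms[1])
  }
})

test_that("pairwise phi equals the one-way result and seeds reproduce p", {
  v <- random_binary_matrix(16, 12, 77)
  m <- marker_matrix(v)
  s <- sample_table(data.frame(
    sample_id = rownames(v), population = rep(c("P1", "P2"), each = 8),
    region = "R", habitat = "meadow", cohort = "AG", x = 0, y = 0))
  pw <- pairwise_phi_st(m, s, "population", n_perm = 99, seed = 3)
  direct <- amova_oneway(pairwise_distance(m), s$population, n_perm = 0)
  expect_identical(pw$phi_st[1], direct$phi_st)
  pw2 <- pairwise_phi_st(m, s, "population", n_perm = 99, seed = 3)
  expect_identical(pw$p, pw2$p)
  expect_equal(attr(pw, "phi_matrix")["P1", "P2"], direct$phi_st)
})

test_that("hierarchical AMOVA matches an independent loop-based oracle", {
  for (seed in 1:3) {
    v <- random_binary_matrix(20, 10, seed + 60)
    pops <- rep(c("P1", "P2", "P3", "P4"), each = 5)
    regions <- rep(c("R", "T"), each = 10)
    d <- pairwise_distance(marker_matrix(v))
    res <- amova_hierarchical(d, regions, pops, n_perm = 0)
    oracle <- oracle_amova_hier(d, regions, pops)
    expect_equal(unname(res$levels$sigma), unname(oracle$sigma),
                 tolerance = 1e-10)
    expect_equal(res$phi_ct, oracle$phi_ct, tolerance = 1e-10)
    expect_equal(res$phi_sc, oracle$phi_sc, tolerance = 1e-10)
    expect_equal(res$phi_st, oracle$phi_st, tolerance = 1e-10)
  }
})

test_that("hierarchical AMOVA flags degenerate nesting", {
  v <- random_binary_matrix(20, 8, 90)
  pops <- rep(c("P1", "P2", "P3", "P4"), each = 5)
  # regions with identical composition -> phi_CT near 0
  regions <- rep(c("R", "T"), 10)[order(rep(1:4, each = 5))]
  d <- pairwise_distance(marker_matrix(v))
  res <- amova_hierarchical(d, rep(c("R", "T", "R", "T"), each = 5), pops,
                            n_perm = 0)
  expect_lt(abs(res$phi_ct), 0.25)
  # one population per region -> flagged unstable
  expect_warning(
    amova_hierarchical(d, pops, pops, n_perm = 0),
    "single population")
  expect_error(amova_hierarchical(d, rep("R", 20), pops, n_perm = 0),
               "at least 2 regions")
})

test_that("PCA centers binary data and orders variance fractions", {
  v <- rbind(s1 = c(1L, 0L), s2 = c(0L, 1L), s3 = c(1L, 1L))
  pc <- pca_scores(marker_matrix(v))
  # oracle: eigendecomposition of the hand-built covariance matrix
  cv <- stats::cov(scale(v, center = TRUE, scale = FALSE))
  eig <- eigen(cv)
  expect_equal(pc$variance_fraction,
               eig$values / sum(eig$values), tolerance = 1e-12)
  expect_equal(abs(as.numeric(pc$scores[, 1])),
               abs(as.numeric(scale(v, TRUE, FALSE) %*% eig$vectors[, 1])),
               tolerance = 1e-12)

  # identical samples score identically; fractions non-increasing, sum <= 1
  v2 <- random_binary_matrix(10, 6, 8)
  v2[2, ] <- v2[1, ]
  pc2 <- pca_scores(marker_matrix(v2))
  expect_equal(pc2$scores[1, ], pc2$scores[2, ])
  expect_true(all(diff(pc2$variance_fraction) <= 1e-12))
  expect_lte(sum(pc2$variance_fraction), 1 + 1e-12)

  # constant matrix -> zero scores and fractions
  pc3 <- pca_scores(marker_matrix(matrix(1L, 4, 3)))
  expect_true(all(pc3$scores == 0))
  expect_true(all(pc3$variance_fraction == 0))
})
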