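test_that("band richness matches hypergeometric hand values", {
  mono <- marker_matrix(matrix(1L, 6, 1))
  expect_equal(band_richness(mono, 3)$Br, 1)

  m <- marker_matrix(matrix(c(1L, 1L, 1L, 0L), 4, 1))  # n1 = 3 of N = 4
  expect_equal(band_richness(m, 2)$Br, 1.5)  # 1 + (1 - C(3,2)/C(4,2))

  # g = N recovers the observed state count exactly
  expect_equal(band_richness(m, 4)$Br, 2)
  expect_equal(band_richness(mono, 6)$Br, 1)

  expect_error(band_richness(m, 5), "exceeds")
  expect_error(band_richness(m, 1), "at least 2")
})

test_that("private band richness matches hand values and symmetry rules", {
  a <- marker_matrix(matrix(c(1L, 1L, 0L, 0L), 4, 1))  # n1 = 2
  b <- marker_matrix(matrix(c(1L, 0L, 0L, 0L), 4, 1))  # n1 = 1
  pb <- private_band_richness(a, b, 2)
  expect_equal(pb[["PBr_a"]], 5 / 6 * (1 - 1 / 2))  # Q_a (1 - Q_b) = 5/12
  expect_equal(pb[["PBr_b"]], 1 / 2 * (1 - 5 / 6))

  fixed <- marker_matrix(matrix(1L, 4, 1))
  absent <- marker_matrix(matrix(0L, 4, 1))
  expect_equal(private_band_richness(fixed, absent, 3),
               c(PBr_a = 1, PBr_b = 0))
  expect_equal(private_band_richness(absent, absent, 3),
               c(PBr_a = 0, PBr_b = 0))

  # identical per-locus counts: symmetric, and exactly zero at g = N
  # (below g = N both groups keep a positive chance of missing a band,
  # so Q_a (1 - Q_b) stays positive)
  v <- random_binary_matrix(8, 6, 3)
  m <- marker_matrix(v)
  pb_sym <- private_band_richness(m, m, 4)
  expect_equal(pb_sym[["PBr_a"]], pb_sym[["PBr_b"]])
  expect_equal(private_band_richness(m, m, 8), c(PBr_a = 0, PBr_b = 0))

  expect_error(private_band_richness(
    m, marker_matrix(v[, 1:3, drop = FALSE]), 4), "locus set")
})

test_that("eMLG and Pu match grouping-based hand values", {
  same <- marker_matrix(matrix(rep(c(1L, 0L), each = 5), 5, 2))
  expect_equal(proportion_unique(same, 3), c(eMLG = 1, Pu = 0))

  v <- rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 1L))  # counts {2, 2}
  pu <- proportion_unique(marker_matrix(v), 2)
  expect_equal(pu[["eMLG"]], 5 / 3)
  expect_equal(pu[["Pu"]], 2 / 3)

  distinct <- marker_matrix(diag(4L))
  expect_equal(proportion_unique(distinct, 4), c(eMLG = 4, Pu = 1))
})

test_that("PLP uses a strict minority-frequency threshold", {
  # one band in 20 at g = N: minority frequency exactly 0.05, not counted
  v <- cbind(c(1L, rep(0L, 19)), rep(c(0L, 1L), 10))
  expect_equal(plp(marker_matrix(v), 20), 50)
  # 1 qualifying locus of 4 at g = N
  v4 <- cbind(rep(c(0L, 1L), 10), rep(0L, 20), rep(1L, 20),
              c(1L, rep(0L, 19)))
  expect_equal(plp(marker_matrix(v4), 20), 25)
})

test_that("closed-form rarefaction agrees with Monte-Carlo subsampling", {
  for (seed in 1:6) {
    n <- sample(5:9, 1)
    g <- sample(2:(n - 1), 1)
    v <- random_binary_matrix(n, 6, seed + 100)
    m <- marker_matrix(v)

    mc <- mc_band_richness(v, g, R = 3000, seed = seed)
    expect_lt(abs(band_richness(m, g)$Br - mc[["mean"]]),
              3 * mc[["se"]] + 1e-9)

    mc2 <- mc_emlg(v, g, R = 3000, seed = seed)
    expect_lt(abs(proportion_unique(m, g)[["eMLG"]] - mc2[["mean"]]),
              3 * mc2[["se"]] + 1e-9)

    vb <- random_binary_matrix(n + 1, 6, seed + 200)
    mc3 <- mc_private_bands(v, vb, g, R = 3000, seed = seed)
    expect_lt(abs(private_band_richness(m, marker_matrix(vb), g)[["PBr_a"]] -
                    mc3[["mean"]]),
              3 * mc3[["se"]] + 1e-9)
  }
})

test_that("Br and eMLG are non-decreasing in the rarefaction size", {
  # (private richness is not monotone in g: a band common in one group but
  # rare in the other contributes Q_a (1 - Q_b), which falls as g grows)
  v <- random_binary_matrix(10, 8, 11)
  m <- marker_matrix(v)
  br <- vapply(2:10, function(g) band_richness(m, g)$Br, numeric(1))
  em <- vapply(2:10, function(g) proportion_unique(m, g)[["eMLG"]], numeric(1))
  expect_true(all(diff(br) >= -1e-12))
  expect_true(all(diff(em) >= -1e-12))
})
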