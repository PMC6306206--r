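make_sb_table <- function(tray_cells) {
  n <- nrow(tray_cells)
  sample_table(data.frame(
    sample_id = sprintf("sb%02d", seq_len(n)), population = "P1",
    region = "R", habitat = "meadow", cohort = "SB",
    x = (tray_cells$x1 + tray_cells$x2) / 2,
    y = (tray_cells$y1 + tray_cells$y2) / 2,
    tray_id = sprintf("T%02d", seq_len(n)),
    tray_x1 = tray_cells$x1, tray_y1 = tray_cells$y1,
    tray_x2 = tray_cells$x2, tray_y2 = tray_cells$y2))
}

test_that("seed-bank samples get tray midpoints and span eligibility", {
  s <- make_sb_table(data.frame(x1 = c(0, 0), y1 = c(0, 0),
                                x2 = c(2, 6), y2 = c(0, 0)))
  co <- sb_coordinates(s, max_pool_span = 4)
  expect_equal(co$x[1], 1)       # midpoint of (0,0) and (2,0)
  expect_equal(co$y[1], 0)
  expect_true(co$eligible[1])
  expect_false(co$eligible[2])   # cells 6 m apart
  expect_true(is.na(co$x[2]))

  # AG coordinates pass through unchanged
  ag <- sample_table(data.frame(
    sample_id = c("a1", "a2"), population = "P1", region = "R",
    habitat = "meadow", cohort = "AG", x = c(3, 5), y = c(7, 1)))
  co_ag <- sb_coordinates(ag)
  expect_equal(co_ag$x, c(3, 5))
  expect_true(all(co_ag$eligible))

  # missing tray coordinates -> excluded with warning
  s_bad <- as.data.frame(s)
  s_bad$tray_x1[1] <- NA
  expect_warning(co2 <- sb_coordinates(sample_table(s_bad)), "missing")
  expect_false(co2$eligible[1])
})

# helper mirroring the class construction, for the pair-count check
distance_class_pairs <- function(co, limits) {
  d <- as.matrix(dist(co))[upper.tri(diag(nrow(co)))]
  idx <- findInterval(d, c(-1e-9, limits), left.open = TRUE)
  idx[idx > length(limits)] <- NA
  idx
}

test_that("correlogram classes, envelopes and p-value bounds behave", {
  set.seed(4)
  # two tight spatial families of near-identical genotypes
  fam <- rbind(matrix(rep(rbinom(20, 1, 0.5), 5), 5, byrow = TRUE),
               matrix(rep(rbinom(20, 1, 0.5), 5), 5, byrow = TRUE))
  fam[cbind(sample(10, 4, TRUE), sample(20, 4, TRUE))] <- 0L  # slight noise
  m <- marker_matrix(fam)
  co <- data.frame(x = c(rnorm(5, 2, 0.5), rnorm(5, 15, 0.5)),
                   y = c(rnorm(5, 2, 0.5), rnorm(5, 15, 0.5)))
  k <- suppressWarnings(kinship_matrix(m, 0.5))
  cg <- correlogram(k, co, n_perm = 199, seed = 1)
  expect_equal(sum(cg$n_pairs), choose(10, 2) -
                 sum(is.na(distance_class_pairs(co, c(4, 8, 12, 16, 20)))))
  expect_false(cg$empty[1])
  # family clustering: first class strongly positive and significant
  expect_gt(cg$mean_fij[1], 0)
  expect_lte(cg$p[1], 0.05)
  # p can never fall below 2/(n_perm + 1) for the two-sided estimator
  expect_gte(min(cg$p, na.rm = TRUE), 2 / (199 + 1) - 1e-12)

  # all individuals at one point: all pairs in class 1, others empty
  co0 <- data.frame(x = rep(1, 10), y = rep(1, 10))
  cg0 <- correlogram(k, co0, n_perm = 0)
  expect_equal(cg0$n_pairs[1], choose(10, 2))
  expect_true(all(cg0$empty[-1]))
})

test_that("Sp arithmetic and the restricted log-distance regression", {
  expect_equal(round(sp_statistic(0.391, -0.428), 3), 0.703)
  expect_equal(sp_statistic(0.5, 0), 0)
  expect_error(sp_statistic(1, -0.1), "undefined")

  ds <- sim_one_pop(seed = 21)
  ad <- ds$populations$P1$adults
  m <- filter_loci(marker_matrix((ad$a1 | ad$a2) * 1L))$matrix
  k <- suppressWarnings(kinship_matrix(m, 0.5))
  co <- data.frame(x = ad$x, y = ad$y)
  res <- sgs_summary(k, co, n_perm = 49, seed = 2)
  expect_equal(res$Sp, -res$b_log / (1 - res$F1))
  # independent slope check: lm over the same restricted pairs
  d <- as.matrix(dist(co))
  ut <- upper.tri(d)
  sel <- d[ut] > 0 & d[ut] <= 20
  fit <- lm(unclass(k)[ut][sel] ~ log(d[ut][sel]))
  expect_equal(res$b_log, unname(coef(fit)[2]), tolerance = 1e-10)

  # rigid translation + rotation of coordinates leaves Sp unchanged
  th <- 0.7
  rot <- data.frame(x = 100 + co$x * cos(th) - co$y * sin(th),
                    y = -50 + co$x * sin(th) + co$y * cos(th))
  res_rot <- sgs_summary(k, rot, n_perm = 0)
  expect_equal(res_rot$Sp, res$Sp, tolerance = 1e-10)

  # degenerate geometry: all positive pairwise distances identical
  two_spots <- data.frame(x = c(0, 0, 3, 3), y = c(0, 0, 0, 0))
  k4 <- unclass(k)[1:4, 1:4]
  expect_error(sgs_summary(structure(k4, class = "kinship_matrix"),
                           two_spots, n_perm = 0), "identical")
})

test_that("raising the assumed inbreeding coefficient shifts Sp only modestly", {
  ds <- sim_one_pop(seed = 33)
  ad <- ds$populations$P1$adults
  m <- filter_loci(marker_matrix((ad$a1 | ad$a2) * 1L))$matrix
  co <- data.frame(x = ad$x, y = ad$y)
  sp <- vapply(c(0.5, 0.7, 0.9), function(f) {
    k <- suppressWarnings(kinship_matrix(m, f))
    sgs_summary(k, co, n_perm = 0)$Sp
  }, numeric(1))
  expect_true(all(is.finite(sp)))
  expect_true(all(sp > 0))                     # structure detected throughout
  expect_lt(max(abs(sp - sp[1])), 0.5 * (abs(sp[1]) + 0.1))
})
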