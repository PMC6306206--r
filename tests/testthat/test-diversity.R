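test_that("diversity table has one valid row per population x cohort", {
  layout <- default_population_layout()[c(1, 5), ]
  cfg <- simulation_config(populations = layout, n_loci = 100,
                           capacity = c(meadow = 60, woodland = 60),
                           n_generations = 8, seed = 5)
  sv <- simulate_survey(cfg)
  m <- filter_loci(sv$markers)$matrix
  tab <- suppressWarnings(diversity_table(m, sv$samples, g = 8, plp_R = 100))
  ok <- !tab$skipped
  expect_true(any(ok))
  expect_true(all(tab$Br[ok] >= 1 & tab$Br[ok] <= 2))
  expect_true(all(tab$PLP[ok] >= 0 & tab$PLP[ok] <= 100))
  expect_true(all(tab$Pu[ok] >= 0 & tab$Pu[ok] <= 1))
  expect_true(all(tab$PBr[ok] >= 0, na.rm = TRUE))
  expect_true(all(tab$g[ok] <= tab$N[ok]))
  expect_false(anyDuplicated(tab[, c("population", "cohort")]) > 0)
})

test_that("identical cohorts give zero private richness and equal Br", {
  v <- random_binary_matrix(24, 10, 9)
  ids_ag <- sprintf("ag%02d", 1:12)
  ids_sb <- sprintf("sb%02d", 1:12)
  vals <- rbind(v[1:12, ], v[1:12, ])
  rownames(vals) <- c(ids_ag, ids_sb)
  m <- marker_matrix(vals)
  s <- sample_table(data.frame(
    sample_id = c(ids_ag, ids_sb), population = "P1", region = "R",
    habitat = "meadow", cohort = rep(c("AG", "SB"), each = 12),
    x = 0, y = 0))
  tab <- diversity_table(m, s, g = 12, plp_R = 50)
  expect_equal(tab$PBr, c(0, 0))
  expect_equal(tab$Br[1], tab$Br[2])
  expect_equal(tab$Pu[1], tab$Pu[2])
})

test_that("log response ratios match closed forms and the t interval", {
  base <- data.frame(
    population = rep(paste0("P", 1:3), each = 2),
    habitat = "meadow", region = "R",
    cohort = rep(c("AG", "SB"), 3),
    Br = 1.2, PLP = 20, PBr = 0.05, Pu = 0.7, skipped = FALSE)

  # SB == AG everywhere -> mean 0, not significant
  rr0 <- ln_response_ratio(base, "Br", "meadow")
  expect_equal(rr0$mean_lnrr, 0)
  expect_false(rr0$significant)
  expect_true(rr0$ci_low <= 0 && rr0$ci_high >= 0)

  # SB = AG / 2 -> mean = -ln 2 exactly
  halved <- base
  halved$Br[halved$cohort == "SB"] <- halved$Br[halved$cohort == "SB"] / 2
  expect_equal(ln_response_ratio(halved, "Br", "meadow")$mean_lnrr, -log(2))

  # hand-computed t interval for lnRR {-0.2, -0.3, -0.4}
  custom <- base
  custom$Pu[custom$cohort == "SB"] <-
    custom$Pu[custom$cohort == "AG"] * exp(c(-0.2, -0.3, -0.4))
  rr <- ln_response_ratio(custom, "Pu", "meadow")
  expect_equal(rr$mean_lnrr, -0.3, tolerance = 1e-10)
  se <- 0.1 / sqrt(3)
  expect_equal(rr$ci_low, -0.3 - qt(0.975, 2) * se, tolerance = 1e-10)
  expect_equal(rr$ci_high, -0.3 + qt(0.975, 2) * se, tolerance = 1e-10)
  expect_true(rr$significant)  # CI [-0.443, -0.157] excludes 0

  # fewer than 2 usable populations
  expect_error(ln_response_ratio(base[1:2, ], "Br", "meadow"), "fewer than 2")

  # zero values dropped with a warning
  z <- base
  z$PBr[1] <- 0
  expect_warning(ln_response_ratio(z, "PBr", "meadow"), "dropped")
})
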