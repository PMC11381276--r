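test_that("cumulative excretion reproduces the reported matrix totals", {
  d <- dose_event("oral", 25)
  iv <- generate_excretion(c(urine = 0.173, bile = 0.00752, feces = 0.0197),
                           k_elim = 0.5, dose_event = d, body_weight = 0.25,
                           sigma = 0)
  s <- cumulative_excretion(iv, d, body_weight = 0.25)
  totals <- setNames(s$totals$percent_of_dose, s$totals$matrix)
  expect_equal(totals[["urine"]], 17.3, tolerance = 1e-6)
  expect_equal(totals[["bile"]], 0.752, tolerance = 1e-6)
  expect_equal(totals[["feces"]], 1.97, tolerance = 1e-6)
  expect_equal(s$total_recovery, 20.022, tolerance = 1e-6)
})

test_that("zero excretion gives an all-zero summary", {
  d <- dose_event("oral", 25)
  iv <- generate_excretion(c(urine = 0, bile = 0), k_elim = 0.5,
                           dose_event = d, body_weight = 0.25)
  s <- cumulative_excretion(iv, d, body_weight = 0.25)
  expect_equal(s$total_recovery, 0)
  expect_true(all(s$curves$cum_percent == 0))
})

test_that("first-order urinary elimination matches the analytic cumulative curve", {
  d <- dose_event("oral", 10)
  iv <- generate_excretion(c(urine = 0.2), k_elim = 0.5, dose_event = d,
                           body_weight = 0.25, sigma = 0)
  s <- cumulative_excretion(iv, d, body_weight = 0.25)
  u <- s$curves[s$curves$matrix == "urine", ]
  expect_equal(u$cum_percent, 100 * 0.2 * (1 - exp(-0.5 * u$time)),
               tolerance = 1e-9)
})

test_that("interval validation catches overlaps, missing volumes and over-recovery", {
  bad <- data.frame(matrix = "urine", t_start = c(0, 1), t_end = c(2, 3),
                    volume_or_weight = 1, conc = 1)
  expect_error(excretion_intervals(bad), "overlapping")
  skip_one <- data.frame(matrix = "urine", t_start = c(0, 2),
                         t_end = c(2, 4), volume_or_weight = c(NA, 1),
                         conc = 1000)
  expect_warning(iv <- excretion_intervals(skip_one), "skipped")
  expect_equal(nrow(iv), 1)
  expect_error(excretion_intervals(data.frame(matrix = "sweat", t_start = 0,
                                              t_end = 1, volume_or_weight = 1,
                                              conc = 1)),
               "urine, bile or feces")
  # a physically impossible recovery (> 100% of dose) warns
  d <- dose_event("oral", 1)
  huge <- data.frame(matrix = "urine", t_start = 0, t_end = 2,
                     volume_or_weight = 10, conc = 1e9)
  expect_warning(cumulative_excretion(huge, d, body_weight = 0.25),
                 "exceeds 100")
})

test_that("feces amounts carry the homogenate dilution factor", {
  d <- dose_event("oral", 25)
  rec <- data.frame(matrix = c("urine", "feces"), t_start = 0, t_end = 24,
                    volume_or_weight = c(10, 10), conc = c(100, 100))
  iv <- excretion_intervals(rec, feces_dilution = 5)
  expect_equal(iv$amount, c(1000, 5000))
})

test_that("cumulative curves are monotone even under noise", {
  d <- dose_event("oral", 25)
  iv <- generate_excretion(c(urine = 0.15, bile = 0.01, feces = 0.02),
                           k_elim = 0.4, dose_event = d, body_weight = 0.25,
                           sigma = 0.05, seed = 9)
  s <- cumulative_excretion(iv, d, body_weight = 0.25)
  for (m in unique(s$curves$matrix)) {
    expect_true(all(diff(s$curves$cum_percent[s$curves$matrix == m]) >= 0))
  }
})

test_that("tissue exposure ratios rank tissues by AUC ratio", {
  plasma <- one_cmt_iv(dose = 25, v = 4, k = 0.5,
                       times = c(0.167, 0.5, 3, 8))
  same <- plasma; same$matrix <- "kidney"
  twice <- plasma; twice$matrix <- "stomach"
  twice$samples$conc <- 2 * twice$samples$conc
  te <- tissue_exposure(list(same, twice), plasma)
  expect_equal(te$kp_obs[te$tissue == "kidney"], 1, tolerance = 1e-12)
  expect_equal(te$kp_obs[te$tissue == "stomach"], 2, tolerance = 1e-12)
  expect_equal(te$tissue[1], "stomach")  # ranked descending

  kp_true <- c(stomach = 12.8, kidney = 7, liver = 6.5, lung = 3, heart = 2,
               muscle = 2.5, fat = 0.36, brain = 0.084)
  tissues <- generate_tissue_profiles(kp_true, plasma)
  rank <- tissue_exposure(tissues, plasma)
  expect_equal(rank$tissue, names(sort(kp_true, decreasing = TRUE)))
  expect_equal(rank$kp_obs, as.numeric(sort(kp_true, decreasing = TRUE)),
               tolerance = 1e-9)
  # common rescaling of all concentrations leaves kp_obs unchanged
  scaled <- lapply(tissues, function(p) { p$samples$conc <- p$samples$conc * 3; p })
  plasma3 <- plasma; plasma3$samples$conc <- plasma3$samples$conc * 3
  expect_equal(tissue_exposure(scaled, plasma3)$kp_obs, rank$kp_obs)
  # degenerate plasma profile
  flat <- plasma; flat$samples$conc[] <- 0
  expect_error(tissue_exposure(tissues, flat), "plasma AUC")
})
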