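test_that("trapezoid AUC matches simple geometry and the analytic oracle", {
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 10, 0), method = "linear"), 10)
  expect_equal(auc_trapezoid(c(0, 4), c(5, 5)), 20)
  t <- seq(0, 12, length.out = 200)
  c_exp <- 100 * exp(-0.5 * t)
  truth <- 200 * (1 - exp(-6))
  expect_lt(abs(auc_trapezoid(t, c_exp, method = "linear") / truth - 1), 1e-3)
  # the log-down rule is exact for a mono-exponential decline
  expect_equal(auc_trapezoid(c(0, 2, 6), 100 * exp(-0.5 * c(0, 2, 6)),
                             method = "linear_up_log_down"),
               200 * (1 - exp(-3)), tolerance = 1e-12)
  expect_error(auc_trapezoid(1, 5), "insufficient")
})

test_that("AUC is additive over interior cut points and monotone in added samples", {
  set.seed(7)
  for (i in 1:20) {
    t <- sort(runif(8, 0, 12))
    c <- runif(8, 0, 100)
    cut <- t[sample(2:7, 1)]
    whole <- auc_trapezoid(t, c, method = "linear")
    left <- auc_trapezoid(t[t <= cut], c[t <= cut], method = "linear")
    right <- auc_trapezoid(t[t >= cut], c[t >= cut], method = "linear")
    expect_equal(left + right, whole, tolerance = 1e-12)
    # appending a non-negative sample never decreases the area
    bigger <- auc_trapezoid(c(t, max(t) + 1), c(c, runif(1, 0, 50)),
                            method = "linear")
    expect_gte(bigger, whole - 1e-12)
  }
})

test_that("lambda-z is exact on a mono-exponential tail", {
  t <- c(4, 6, 8, 10, 12)
  fit <- fit_lambda_z(t, 100 * exp(-0.66 * t), exclude_tmax = FALSE)
  expect_equal(fit$lambda_z, 0.66, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
})

test_that("lambda-z under multiplicative noise covers the truth in its own CI", {
  t <- c(2, 4, 6, 8, 10, 12)
  set.seed(11)
  conc <- 100 * exp(-0.66 * t) * exp(rnorm(length(t), 0, 0.1))
  fit <- fit_lambda_z(t, conc, exclude_tmax = FALSE)
  lm_fit <- lm(log(conc[match(fit$indices, seq_along(t))]) ~ t[fit$indices])
  ci <- -rev(confint(lm_fit)[2, ])
  expect_gte(0.66, ci[1])
  expect_lte(0.66, ci[2])
})

test_that("best-fit window on a biexponential profile matches brute enumeration", {
  t <- c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12)
  conc <- 800 * exp(-2.5 * t) + 100 * exp(-0.3 * t)
  fit <- fit_lambda_z(t, conc, exclude_tmax = FALSE)
  # independent brute-force enumeration of terminal windows with stats::lm
  best <- list(adj = -Inf)
  for (start in 1:(length(t) - 2)) {
    idx <- start:length(t)
    m <- lm(log(conc[idx]) ~ t[idx])
    adj <- summary(m)$adj.r.squared
    if (coef(m)[2] < 0 &&
        (adj > best$adj + 1e-12 ||
         (abs(adj - best$adj) <= 1e-12 && length(idx) > length(best$idx)))) {
      best <- list(adj = adj, idx = idx, lz = -coef(m)[[2]])
    }
  }
  expect_equal(fit$lambda_z, best$lz, tolerance = 1e-10)
  expect_equal(sort(fit$indices), best$idx)
  expect_lt(fit$lambda_z, 2.5)       # confined to the terminal phase
  expect_error(fit_lambda_z(c(1, 2), c(10, 5)), "insufficient")
})

test_that("full NCA recovers the closed-form one-compartment parameters", {
  p <- one_cmt_iv(dose = 10, v = 3, k = 0.66)
  r <- run_nca(p)
  expect_equal(r$cl, 3 * 0.66, tolerance = 0.01)
  expect_equal(r$vz, 3, tolerance = 0.01)
  expect_equal(r$t_half, log(2) / 0.66, tolerance = 0.01)
  expect_gte(r$auc_inf, r$auc_last)
  expect_equal(r$t_half, log(2) / r$lambda_z)
  expect_equal(r$vz, r$cl / r$lambda_z, tolerance = 1e-10)
  expect_false(r$apparent)
  expect_lt(r$extrapolated_fraction, 1)
})

test_that("reported iv means are internally consistent: Vz = CL * t1/2 / ln 2", {
  ref <- reported_reference_values()$rat_pk
  iv_male <- ref[ref$group == "iv_10" & ref$sex == "male", ]
  expect_equal(iv_male$cl * iv_male$t_half / log(2), iv_male$vd,
               tolerance = 0.03)
})

test_that("NCA on noise-free simulated subjects recovers CL, Vz, T1/2 within 2%", {
  set.seed(101)
  for (i in 1:100) {
    cl <- exp(runif(1, log(0.5), log(8)))
    v <- exp(runif(1, log(1), log(10)))
    k <- cl / v
    times <- seq(0, 6 / k, length.out = 120)
    r <- run_nca(one_cmt_iv(dose = 10, v = v, k = k, times = times))
    expect_equal(r$cl, cl, tolerance = 0.02)
    expect_equal(r$vz, v, tolerance = 0.02)
    expect_equal(r$t_half, log(2) / k, tolerance = 0.02)
  }
})

test_that("oral NCA flags apparent parameters and reports absorption-inclusive MRT", {
  p <- generate_profiles(1, "oral", 25, pars = list(CL = 3, V = 4, ka = 2),
                         schedule = seq(0, 24, by = 0.05), seed = 1)[[1]]
  r <- run_nca(p)
  expect_true(r$apparent)
  # MRT includes the mean absorption time 1/ka on top of V/CL
  expect_equal(r$mrt_inf, 4 / 3 + 1 / 2, tolerance = 0.02)
  expect_error(run_nca(conc_profile("x", "rat",
                                    dose = dose_event("oral", 10),
                                    time = c(0, 1), conc = c(0, 50))),
               "insufficient")
})

test_that("iv profiles with a pre-dose zero are back-extrapolated to C0", {
  k <- 0.66; v <- 3
  times <- c(0, 0.0333, 0.0833, 0.25, 0.5, 1, 2, 4, 6, 8, 10, 12)
  conc <- 1000 * 10 / v * exp(-k * times)
  conc[1] <- 0  # pre-dose record
  r <- run_nca(conc_profile("x", "rat", dose = dose_event("iv_bolus", 10),
                            time = times, conc = conc))
  expect_equal(r$cl, v * k, tolerance = 0.01)
})

test_that("bioavailability reproduces the reported quotients", {
  expect_equal(bioavailability(765, 10, 3217, 10), 23.8, tolerance = 0.001)
  expect_equal(bioavailability(14300, 10, 11070, 3), 38.8, tolerance = 0.002)
  expect_equal(bioavailability(500, 10, 1000, 20), 100)
  expect_error(bioavailability(0, 10, 100, 10), "positive")
})

test_that("dose proportionality and accumulation ratios match the reported values", {
  expect_equal(dose_proportionality(c(402, 2000, 6730)),
               c(1, 4.98, 16.74), tolerance = 0.001)
  expect_equal(dose_proportionality(c(765, 3367, 11633)),
               c(1, 4.40, 15.21), tolerance = 0.001)
  expect_equal(dose_proportionality(c(7, 7, 7)), c(1, 1, 1))
  expect_error(dose_proportionality(c(0, 5)), "> 0")
  expect_equal(signif(accumulation_ratio(1169, 2000), 2), 0.58)
  expect_equal(signif(accumulation_ratio(3310, 3367), 2), 0.98)
  expect_equal(accumulation_ratio(3.3, 3.3), 1)
  expect_error(accumulation_ratio(1, 0), "> 0")
})

test_that("group summaries report mean, SD and drop SD at n = 1", {
  ps <- generate_profiles(3, "iv_bolus", 10, pars = list(CL = 3, V = 4),
                          sigma = 0.05, seed = 5)
  res <- lapply(ps, run_nca)
  summ <- nca_group_summary(res)
  cl_row <- summ[summ$parameter == "cl", ]
  expect_equal(cl_row$n, 3)
  expect_false(is.na(cl_row$sd))
  one <- nca_group_summary(res[1])
  expect_true(all(is.na(one$sd)))
})
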