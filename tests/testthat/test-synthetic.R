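test_that("noise-free generation equals the closed form exactly", {
  p <- generate_profiles(1, "iv_bolus", 10, pars = list(CL = 2, V = 4),
                         sigma = 0, seed = 1)[[1]]
  t <- p$samples$time
  expect_equal(p$samples$conc, 1000 * 10 / 4 * exp(-0.5 * t), tolerance = 1e-12)
})

test_that("generators are pure functions of the seed", {
  a <- generate_profiles(5, "oral", 25, pars = list(CL = 3, V = 4, ka = 2),
                         sigma = 0.2, bsv_cv = 0.3, seed = 7)
  b <- generate_profiles(5, "oral", 25, pars = list(CL = 3, V = 4, ka = 2),
                         sigma = 0.2, bsv_cv = 0.3, seed = 7)
  for (i in seq_along(a)) expect_identical(a[[i]]$samples, b[[i]]$samples)
  expect_identical(generate_dialysis(73.3, 0.03, seed = 4),
                   generate_dialysis(73.3, 0.03, seed = 4))
  expect_identical(generate_excretion(c(urine = 0.2), 0.5,
                                      dose_event("oral", 25), 0.25,
                                      sigma = 0.1, seed = 2),
                   generate_excretion(c(urine = 0.2), 0.5,
                                      dose_event("oral", 25), 0.25,
                                      sigma = 0.1, seed = 2))
})

test_that("NCA on many noisy subjects recovers the generating clearance", {
  ps <- generate_profiles(200, "iv_bolus", 10, pars = list(CL = 3, V = 4),
                          sigma = 0.1, schedule = seq(0, 12, by = 0.25),
                          seed = 20)
  cls <- vapply(ps, function(p) run_nca(p)$cl, numeric(1))
  expect_lt(abs(mean(cls) / 3 - 1), 0.03)
})

test_that("microsomal generator round-trips through fit_ke", {
  a <- generate_microsomal_assay(0.0161, sigma = 0)
  expect_equal(fit_ke(a$time_min, a$remaining)$ke, 0.0161, tolerance = 1e-12)
  z <- generate_microsomal_assay(0, sigma = 0)
  expect_true(all(z$remaining == 100))
})

test_that("dialysis generator round-trips through binding_summary", {
  d0 <- generate_dialysis(73.3, sigma = 0, species = "human")
  expect_equal(binding_summary(d0)$by_species$bound_avg, 73.3,
               tolerance = 1e-12)
  free <- generate_dialysis(0, sigma = 0)
  expect_equal(free$c_free, free$c_total)
  dn <- generate_dialysis(73.3, sigma = 0.03, n_replicates = 20, seed = 13)
  expect_lt(abs(binding_summary(dn)$by_species$bound_avg - 73.3), 1)
})

test_that("two-compartment profiles show a distribution and a terminal phase", {
  pars <- list(CL = 2, V1 = 1, V2 = 4, Q_dist = 3)
  p <- generate_profiles(1, "iv_bolus", 10, model = "two_compartment",
                         pars = pars, schedule = seq(0, 48, by = 0.05),
                         seed = 1)[[1]]
  r <- run_nca(p)
  # terminal slope is the slow macro rate, clearance still D/AUC = CL
  expect_equal(r$cl, 2, tolerance = 0.02)
  k10 <- 2; k12 <- 3; k21 <- 3 / 4   # rates for V1 = 1
  s <- k10 + k12 + k21
  beta <- (s - sqrt(s^2 - 4 * k21 * k10)) / 2
  expect_equal(r$lambda_z, beta, tolerance = 0.02)
})

test_that("generator configs are validated", {
  expect_error(generate_profiles(1, "oral", 10, pars = list(CL = 1, V = 1, ka = 1),
                                 schedule = c(1, 1, 2)),
               "strictly increasing")
  expect_error(generate_microsomal_assay(-0.1), ">= 0")
  expect_error(generate_dialysis(120), "0, 100")
  expect_error(generate_excretion(c(urine = 0.8, feces = 0.5), 0.5,
                                  dose_event("oral", 10), 0.25),
               "<= 1")
})
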