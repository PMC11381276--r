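test_that("bound percent follows the dialysis formula and is scale invariant", {
  expect_equal(bound_percent(50, 50), 0)
  expect_equal(bound_percent(50, 0), 100)
  expect_equal(bound_percent(100, 13.5), 86.5)
  set.seed(3)
  for (i in 1:20) {
    ct <- runif(1, 1, 100); cf <- runif(1, 0, ct); lam <- runif(1, 0.1, 10)
    expect_equal(bound_percent(ct, cf), bound_percent(lam * ct, lam * cf))
  }
  expect_error(bound_percent(0, 1), "> 0")
  expect_warning(b <- bound_percent(10, 12), "exceeds")
  expect_lt(b, 0)
})

test_that("binding summary reproduces the reported across-level averages", {
  ref <- reported_reference_values()$binding
  meas <- data.frame(species = ref$species, nominal_conc = ref$nominal_conc,
                     c_total = 100, c_free = 100 * (1 - ref$bound_mean / 100))
  s <- binding_summary(meas)$by_species
  avg <- setNames(s$bound_avg, s$species)
  expect_equal(avg[["human"]], 73.3, tolerance = 0.001)
  expect_equal(avg[["rat"]], 39.2, tolerance = 0.001)
  expect_equal(avg[["mouse"]], 49.3, tolerance = 0.001)
  expect_equal(avg[["dog"]], 87.4, tolerance = 0.001)
  fup <- setNames(s$fup, s$species)
  expect_equal(fup[["rat"]], 0.61, tolerance = 0.005)
  # single level: the average is that level
  one <- binding_summary(data.frame(species = "rat", nominal_conc = 1,
                                    c_total = 10, c_free = 4))
  expect_equal(one$by_species$bound_avg, 60)
  expect_error(binding_summary(data.frame()), "columns")
})

test_that("ke regression is exact on noise-free decay and flags flat profiles", {
  t <- c(0, 6, 15, 30, 60, 120)
  fit <- fit_ke(t, 100 * exp(-0.0161 * t))
  expect_equal(fit$ke, 0.0161, tolerance = 1e-12)
  flat <- fit_ke(t, rep(100, 6))
  expect_equal(flat$ke, 0)
  expect_true(flat$non_metabolized)
  expect_error(fit_ke(c(0, 6), c(100, 90)), "insufficient")
  expect_warning(fit_ke(c(0, 6, 15, 30), c(100, 50, 0, 25)), "excluded")
})

test_that("ke recovery from noisy synthetic assays is nearly unbiased", {
  kes <- vapply(1:500, function(s) {
    a <- generate_microsomal_assay(0.0161, sigma = 0.05, seed = s)
    fit_ke(a$time_min, a$remaining)$ke
  }, numeric(1))
  expect_lt(abs(mean(kes) / 0.0161 - 1), 0.02)
})

test_that("the IVIVE chain reproduces the reported microsomal table", {
  rat <- ivive_chain(0.0161, "rat")
  expect_equal(signif(rat$t_half, 3), 43.0)
  expect_equal(rat$clint, 28.9, tolerance = 0.002)
  expect_equal(rat$clh, 18.9, tolerance = 0.003)
  expect_equal(rat$er, 0.343, tolerance = 0.001)
  hum <- ivive_chain(0.0149, "human")
  expect_equal(hum$clint, 18.7, tolerance = 0.001)
  expect_equal(hum$clh, 9.82, tolerance = 0.001)
  expect_equal(hum$er, 0.474, tolerance = 0.001)
  expect_equal(ivive_chain(0.0887, "monkey")$t_half, 7.81, tolerance = 0.001)
})

test_that("the chain respects the well-stirred limits and stays consistent", {
  # ke = 0: nothing is cleared, half-life censored to infinity
  z <- ivive_chain(0, "rat")
  expect_equal(c(z$clint, z$clh, z$er), c(0, 0, 0))
  expect_equal(z$t_half, Inf)
  # enormous intrinsic clearance: extraction approaches 1, CLh -> Q
  big <- ivive_chain(1e6, "rat")
  expect_equal(big$er, 1, tolerance = 1e-4)
  expect_equal(big$clh, species_constants("rat")$q_h, tolerance = 1e-3)
  # ER bounded and monotone in ke; CLh == ER * Q to machine precision
  last <- -1
  for (ke in c(0, 1e-4, 1e-3, 0.01, 0.1, 1, 10)) {
    for (fub in c(0.2, 1)) {
      r <- ivive_chain(ke, "dog", fub = fub)
      expect_gte(r$er, 0); expect_lt(r$er, 1)
      expect_equal(r$clh, r$er * species_constants("dog")$q_h)
    }
    r1 <- ivive_chain(ke, "dog")
    expect_gt(r1$er + 1e-15, last)
    last <- r1$er
  }
  expect_error(ivive_chain(-1, "rat"), ">= 0")
})

test_that("metabolite profiles normalize to 100% over detected peaks", {
  rec <- data.frame(metabolite_id = c("M0", "M1", "M2"),
                    peak_area = c(3, 1, NA))
  prof <- metabolite_profile(rec)
  expect_equal(prof$proportion, c(75, 25, NA))
  one <- metabolite_profile(data.frame(metabolite_id = "M0", peak_area = 42))
  expect_equal(one$proportion, 100)
  expect_error(metabolite_profile(data.frame(metabolite_id = "M0",
                                             peak_area = NA)),
               "empty")
  # the reported per-species proportions re-sum to 100 within 0.2
  met <- reported_reference_values()$metabolites
  for (sp in c("mouse", "rat", "dog", "monkey", "human")) {
    expect_equal(sum(met[[sp]], na.rm = TRUE), 100, tolerance = 0.2 / 100)
  }
})

test_that("microsomal controls gate on the stated thresholds", {
  qc <- microsome_qc(positive_remaining = 0.00338, negative_remaining = 108)
  expect_true(all(qc$pass))
  bad <- microsome_qc(positive_remaining = 50, negative_remaining = 60)
  expect_false(any(bad$pass))
})
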