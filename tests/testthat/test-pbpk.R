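base_rat_model <- function(clint = 28.672, renal = 7.5, ka = 4, fa = 1) {
  build_pbpk_model(deg_azm_card(), species_physiology("rat"),
                   clint_scaled = clint, renal_cl = renal, ka = ka, fa = fa)
}

test_that("mass balance holds to 1e-6 relative at every output time", {
  m <- base_rat_model()
  for (route in c("iv_bolus", "oral")) {
    s <- simulate_pbpk(m, dose = 25, route = route, duration = 12, dt = 0.05)
    expect_lt(s$mass_balance_error, 1e-6)
    amt <- as.matrix(s$trajectory[setdiff(names(s$trajectory),
                                          c("time", "plasma_conc"))])
    expect_true(all(amt >= 0))
  }
})

test_that("a zero dose yields an all-zero trajectory", {
  s <- simulate_pbpk(base_rat_model(), dose = 0, route = "iv_bolus",
                     duration = 2, dt = 0.1)
  expect_equal(max(abs(as.matrix(s$trajectory[-1]))), 0)
})

test_that("the model is linear: doubling the dose doubles Cmax and AUC", {
  m <- base_rat_model()
  s1 <- simulate_pbpk(m, dose = 10, route = "oral", duration = 12, dt = 0.05)
  s2 <- simulate_pbpk(m, dose = 20, route = "oral", duration = 12, dt = 0.05)
  expect_equal(s2$cmax / s1$cmax, 2, tolerance = 1e-6)
  expect_equal(s2$auc / s1$auc, 2, tolerance = 1e-6)
})

test_that("halving solver tolerances moves the AUC by less than 0.1%", {
  m <- base_rat_model()
  s1 <- simulate_pbpk(m, 25, "oral", duration = 12, dt = 0.05)
  s2 <- simulate_pbpk(m, 25, "oral", duration = 12, dt = 0.05,
                      rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(s2$auc / s1$auc - 1), 1e-3)
})

test_that("with flows >> clearance and uniform Kp the body is one compartment", {
  phys <- scaled_flow_physiology(1000)
  card <- deg_azm_card(); card$fup <- c(rat = 1)
  m <- build_pbpk_model(card, phys, clint_scaled = 5, renal_cl = 5,
                        kp = uniform_kp(1))
  s <- simulate_pbpk(m, dose = 10, route = "iv_bolus", duration = 48,
                     dt = 0.01)
  tr <- s$trajectory
  r <- run_nca(conc_profile("sim", "rat", dose = dose_event("iv_bolus", 10),
                            time = tr$time[-1], conc = tr$plasma_conc[-1]))
  # in the flow-dominated limit hepatic extraction vanishes and total
  # clearance approaches CLint + CL_R; V approaches sum(Kp V_T) + V_blood
  cl_expect <- (5 + 5) * 60 / 1000
  v_expect <- sum(phys$organs$volume) + 0.074
  expect_equal(r$cl, cl_expect, tolerance = 0.05)
  expect_equal(r$vz, v_expect, tolerance = 0.05)
})

test_that("without clearance the drug conserves and equilibrates to dose/V", {
  m <- base_rat_model(clint = 0, renal = 0)
  expect_warning(s <- simulate_pbpk(m, dose = 10, route = "iv_bolus",
                                    duration = 100, dt = 0.1),
                 "non-eliminating")
  expect_lt(s$mass_balance_error, 1e-6)
  # uniform-Kp variant: equilibrium plasma concentration is dose over the
  # flow-connected volume
  m1 <- build_pbpk_model(deg_azm_card(), species_physiology("rat"),
                         clint_scaled = 0, renal_cl = 0, kp = uniform_kp(1))
  expect_warning(s1 <- simulate_pbpk(m1, dose = 10, route = "iv_bolus",
                                     duration = 200, dt = 0.5))
  v_tot <- sum(species_physiology("rat")$organs$volume) + 0.074
  c_eq <- 1000 * (10 * 0.25) / (v_tot * 0.25)  # ng/mL
  expect_equal(utils::tail(s1$trajectory$plasma_conc, 1), c_eq,
               tolerance = 1e-3)
})

test_that("model construction validates topology and inputs", {
  phys <- species_physiology("rat")
  phys$organs$flow[phys$organs$organ == "lung"] <- 1
  expect_error(build_pbpk_model(deg_azm_card(), phys, 10, 5, ka = 1),
               "topology")
  expect_error(build_pbpk_model(deg_azm_card(), species_physiology("rat"),
                                -1, 5), ">= 0")
  expect_error(simulate_pbpk(base_rat_model(ka = NA_real_), 10, "oral"),
               "ka")
  card <- deg_azm_card(); card$fup <- c(mouse = 0.5)
  expect_error(build_pbpk_model(card, species_physiology("rat"), 10, 5),
               "fup")
})

test_that("fold-ratio validation applies the 0.5-2.0 band", {
  obs <- data.frame(scenario = c("a", "b"), cmax = c(100, 200),
                    auc = c(1000, 2000))
  v <- validate_against_observed(obs, obs)
  expect_true(v$pass)
  expect_true(all(v$table$fold_ratio == 1))
  pred <- obs; pred$cmax[1] <- 201  # 2.01-fold
  v2 <- validate_against_observed(pred, obs)
  expect_false(v2$pass)
  expect_equal(sum(!v2$table$pass), 1)
  expect_error(validate_against_observed(
    data.frame(scenario = "c", cmax = 1, auc = 1), obs), "pairing")
})

test_that("human dose escalation is sorted, proportional and reproducible", {
  rat <- rat_pbpk_model()
  hum <- human_pbpk_model(rat = rat)
  esc <- human_dose_escalation(hum$model, doses_mg = c(30, 5, 15),
                               duration = 24, dt = 0.05)
  expect_equal(esc$summary$dose_mg, c(5, 15, 30))
  expect_equal(esc$summary$auc_ratio, c(1, 3, 6), tolerance = 1e-6)
  esc2 <- human_dose_escalation(hum$model, doses_mg = c(30, 5, 15),
                                duration = 24, dt = 0.05)
  expect_identical(esc$summary, esc2$summary)
})
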