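# Seeded synthetic-data generators.
#
# Every generator is a pure function of its arguments including the
# seed; noise is multiplicative lognormal (concentrations are positive
# and assay CVs are relative). With sigma = 0 the closed forms are
# reproduced to machine precision, the basis of the round-trip tests.

# closed-form plasma concentration, one- or two-compartment disposition
compartmental_conc <- function(t, route, dose, model, pars) {
  if (model == "one_compartment") {
    v <- pars$V; k <- pars$CL / v
    if (route == "iv_bolus") {
      1000 * dose / v * exp(-k * t)                    # mg/kg / (L/kg) -> ng/mL
    } else {
      ka <- pars$ka; f <- if (is.null(pars$F)) 1 else pars$F
      if (abs(ka - k) < 1e-12) {
        1000 * f * dose / v * k * t * exp(-k * t)
      } else {
        1000 * f * dose * ka / (v * (ka - k)) * (exp(-k * t) - exp(-ka * t))
      }
    }
  } else {
    # two-compartment macro constants from CL, V1, V2, Q_dist
    k10 <- pars$CL / pars$V1
    k12 <- pars$Q_dist / pars$V1
    k21 <- pars$Q_dist / pars$V2
    s <- k10 + k12 + k21
    beta <- (s - sqrt(s^2 - 4 * k21 * k10)) / 2
    alpha <- k21 * k10 / beta
    if (route == "iv_bolus") {
      a <- dose / pars$V1 * (alpha - k21) / (alpha - beta)
      b <- dose / pars$V1 * (k21 - beta) / (alpha - beta)
      1000 * (a * exp(-alpha * t) + b * exp(-beta * t))
    } else {
      ka <- pars$ka; f <- if (is.null(pars$F)) 1 else pars$F
      c1 <- ka * (k21 - alpha) / ((ka - alpha) * (beta - alpha))
      c2 <- ka * (k21 - beta) / ((ka - beta) * (alpha - beta))
      c3 <- ka * (k21 - ka) / ((alpha - ka) * (beta - ka))
      1000 * f * dose / pars$V1 *
        (c1 * exp(-alpha * t) + c2 * exp(-beta * t) + c3 * exp(-ka * t))
    }
  }
}

#' Default in vivo sampling schedules
#'
#' The dense 0-12 h plasma schedule used by the rat and dog studies
#' (pre-dose 0 plus 0.0333-12 h after an iv bolus; oral schedules start
#' at 0.0833 h).
#'
#' @param route "iv_bolus" or "oral".
#' @return numeric vector of times, h.
#' @export
default_schedule <- function(route = c("iv_bolus", "oral")) {
  route <- match.arg(route)
  iv <- c(0, 0.0333, 0.0833, 0.25, 0.5, 1, 2, 4, 6, 8, 10, 12)
  if (route == "iv_bolus") iv else setdiff(iv, 0.0333)
}

#' Generate concentration-time profiles
#'
#' Closed-form compartmental concentrations at the schedule times,
#' multiplied by lognormal residual error; per-subject parameters drawn
#' lognormally around the typical values with the given between-subject
#' CVs. Concentrations below the LLOQ are flagged BLQ and recorded as 0.
#'
#' @param n_subjects number of subjects.
#' @param route,dose dosing (mg/kg).
#' @param model "one_compartment" or "two_compartment".
#' @param pars typical parameter list: CL and V (one-compartment) or
#'   CL, V1, V2, Q_dist (two-compartment), plus ka and F for oral
#'   dosing. Units L/h/kg, L/kg, 1/h.
#' @param sigma lognormal residual SD (0 = noise-free).
#' @param bsv_cv between-subject CV applied to every parameter
#'   (default 0).
#' @param schedule sampling times, h (default
#'   \code{\link{default_schedule}}).
#' @param lloq lower limit of quantification, ng/mL.
#' @param species,sex profile metadata.
#' @param id_prefix prefix for the generated subject ids (keep unique
#'   across dose groups written to one file).
#' @param seed RNG seed.
#' @return list of \code{\link{conc_profile}} objects.
#' @export
generate_profiles <- function(n_subjects, route, dose,
                              model = c("one_compartment", "two_compartment"),
                              pars, sigma = 0, bsv_cv = 0, schedule = NULL,
                              lloq = 0, species = "rat", sex = "male",
                              id_prefix = "S", seed = 1) {
  model <- match.arg(model)
  route <- match.arg(route, c("iv_bolus", "oral"))
  if (is.null(schedule)) schedule <- default_schedule(route)
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing",
                                     call. = FALSE)
  stopifnot(sigma >= 0, bsv_cv >= 0)
  set.seed(seed)
  numeric_pars <- names(pars)[vapply(pars, is.numeric, logical(1))]
  lapply(seq_len(n_subjects), function(i) {
    p_i <- pars
    if (bsv_cv > 0) {
      sd_b <- sqrt(log(1 + bsv_cv^2))
      for (nm in setdiff(numeric_pars, "F")) {
        p_i[[nm]] <- pars[[nm]] * exp(stats::rnorm(1, -sd_b^2 / 2, sd_b))
      }
    }
    conc <- compartmental_conc(schedule, route, dose, model, p_i)
    if (sigma > 0) conc <- conc * exp(stats::rnorm(length(conc), 0, sigma))
    conc[schedule == 0 & route == "oral"] <- 0
    blq <- conc < lloq
    conc[blq] <- 0
    conc_profile(subject_id = sprintf("%s%03d", id_prefix, i), species = species,
                 sex = sex, matrix = "plasma",
                 dose = dose_event(route, dose), time = schedule,
                 conc = conc, blq = blq, lloq = lloq)
  })
}

#' Generate a microsomal stability assay
#'
#' Remaining\% = 100 exp(-ke t) with lognormal error; t = 0 is fixed at
#' 100\% by definition.
#'
#' @param ke_true true elimination rate constant, 1/min.
#' @param sigma lognormal residual SD.
#' @param schedule incubation times, min (default the 0-120 min design;
#'   the fast-metabolizer design is \code{c(0, 3, 6, 9, 15, 30)}).
#' @param n_replicates replicates per timepoint.
#' @param seed RNG seed.
#' @return data.frame with columns \code{time_min}, \code{replicate},
#'   \code{remaining}.
#' @export
generate_microsomal_assay <- function(ke_true, sigma = 0,
                                      schedule = c(0, 6, 15, 30, 60, 120),
                                      n_replicates = 1, seed = 1) {
  if (ke_true < 0) stop("ke_true must be >= 0", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(time_min = schedule, replicate = seq_len(n_replicates))
  rem <- 100 * exp(-ke_true * grid$time_min)
  if (sigma > 0) {
    noise <- exp(stats::rnorm(nrow(grid), 0, sigma))
    noise[grid$time_min == 0] <- 1
    rem <- rem * noise
  }
  data.frame(grid, remaining = rem)
}

#' Generate equilibrium dialysis measurements
#'
#' c_total at each nominal level, c_free = c_total (1 - bound/100),
#' both perturbed multiplicatively.
#'
#' @param bound_true true percent bound (0-100).
#' @param sigma lognormal residual SD.
#' @param levels nominal concentrations, ug/mL (default the 1/4/20
#'   three-level design).
#' @param n_replicates replicates per level.
#' @param species label carried into the output.
#' @param seed RNG seed.
#' @return data.frame compatible with \code{\link{binding_summary}}.
#' @export
generate_dialysis <- function(bound_true, sigma = 0, levels = c(1, 4, 20),
                              n_replicates = 3, species = "rat", seed = 1) {
  if (bound_true < 0 || bound_true > 100) {
    stop("bound_true must be in [0, 100]", call. = FALSE)
  }
  set.seed(seed)
  grid <- expand.grid(nominal_conc = levels, replicate = seq_len(n_replicates))
  c_total <- grid$nominal_conc * 1000          # ug/mL -> ng/mL
  c_free <- c_total * (1 - bound_true / 100)
  if (sigma > 0) {
    c_total <- c_total * exp(stats::rnorm(nrow(grid), 0, sigma))
    c_free <- c_free * exp(stats::rnorm(nrow(grid), 0, sigma))
  }
  data.frame(species = species, grid, c_total = c_total, c_free = c_free)
}

#' Generate interval excretion records
#'
#' First-order appearance in each matrix: the amount excreted over
#' (t1, t2) is fe * dose * (exp(-k t1) - exp(-k t2)), perturbed
#' multiplicatively. Concentrations are back-computed from a nominal
#' collection volume so the records exercise the same conc x volume
#' path as real data.
#'
#' @param fe_by_matrix named vector of fractions of dose ultimately
#'   excreted per matrix (urine/bile/feces), summing to <= 1.
#' @param k_elim first-order elimination rate constant, 1/h.
#' @param dose_event a \code{\link{dose_event}}.
#' @param body_weight kg.
#' @param sigma lognormal residual SD.
#' @param schedules named list of interval end-time vectors per matrix
#'   (defaults mirror the 0-96 h urine/feces and 0-72 h bile designs).
#' @param seed RNG seed.
#' @return data.frame of interval records (see
#'   \code{\link{excretion_intervals}}), with feces concentrations on
#'   the homogenate scale (1:5 dilution).
#' @export
generate_excretion <- function(fe_by_matrix, k_elim, dose_event, body_weight,
                               sigma = 0, schedules = NULL, seed = 1) {
  if (sum(fe_by_matrix) > 1 + 1e-12) stop("sum of fe must be <= 1", call. = FALSE)
  if (is.null(schedules)) {
    schedules <- list(
      urine = c(2, 4, 6, 8, 12, 24, 30, 48, 72, 96),
      feces = c(6, 12, 24, 30, 48, 72, 96),
      bile = c(2, 4, 6, 8, 12, 24, 30, 48, 72)
    )
  }
  set.seed(seed)
  dose_ng <- dose_event$dose_per_bw * body_weight * 1e6
  out <- do.call(rbind, lapply(names(fe_by_matrix), function(m) {
    ends <- schedules[[m]]
    starts <- c(0, ends[-length(ends)])
    amount <- fe_by_matrix[[m]] * dose_ng *
      (exp(-k_elim * starts) - exp(-k_elim * ends))
    if (sigma > 0) amount <- amount * exp(stats::rnorm(length(amount), 0, sigma))
    vol <- pmax(diff(c(0, ends)), 0.5)           # nominal mL (or g) collected
    dil <- if (m == "feces") 5 else 1
    data.frame(matrix = m, t_start = starts, t_end = ends,
               volume_or_weight = vol, conc = amount / (vol * dil),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a tissue-distribution data set with prescribed Kp values
#'
#' Tissue concentration curves proportional to the plasma curve scaled
#' by each prescribed Kp, sampled on the sparse tissue schedule.
#'
#' @param kp_true named vector of true tissue:plasma ratios.
#' @param plasma_profile a plasma \code{\link{conc_profile}}; tissue
#'   samples are taken at \code{schedule}.
#' @param schedule tissue sampling times, h (default
#'   \code{c(0.167, 0.5, 3, 8)}).
#' @param sigma lognormal residual SD.
#' @param seed RNG seed.
#' @return list of tissue \code{\link{conc_profile}} objects.
#' @export
generate_tissue_profiles <- function(kp_true, plasma_profile,
                                     schedule = c(0.167, 0.5, 3, 8),
                                     sigma = 0, seed = 1) {
  set.seed(seed)
  s <- plasma_profile$samples
  plasma_at <- stats::approx(s$time, s$conc, xout = schedule, rule = 2)$y
  lapply(names(kp_true), function(tis) {
    conc <- kp_true[[tis]] * plasma_at
    if (sigma > 0) conc <- conc * exp(stats::rnorm(length(conc), 0, sigma))
    conc_profile(subject_id = plasma_profile$subject_id,
                 species = plasma_profile$species, sex = plasma_profile$sex,
                 matrix = tis, dose = plasma_profile$dose,
                 time = schedule, conc = conc)
  })
}
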