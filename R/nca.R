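# Non-compartmental analysis engine.
#
# Conventions: time h, concentration ng/mL, dose mg/kg, so AUC is
# h*ng/mL, CL = 1000 * dose/AUC_inf in L/h/kg and Vz = CL/lambda_z in
# L/kg. For oral profiles CL and Vz are apparent (per-F) and flagged.

#' Trapezoidal AUC over successive quantifiable points
#'
#' \code{linear} uses the plain trapezoid on every segment;
#' \code{linear_up_log_down} (the usual NCA default) switches to the
#' log-trapezoid on declining segments where both concentrations are
#' positive.
#'
#' @param time,conc numeric vectors (h, ng/mL), times strictly
#'   increasing.
#' @param method "linear_up_log_down" (default) or "linear".
#' @param upper_time integrate only over samples with
#'   \code{time <= upper_time} (default: all).
#' @param moment 0 for AUC, 1 for AUMC (trapezoids of t*C).
#' @return area in h*ng/mL (or h^2*ng/mL for \code{moment = 1}).
#' @export
auc_trapezoid <- function(time, conc, method = c("linear_up_log_down", "linear"),
                          upper_time = Inf, moment = 0) {
  method <- match.arg(method)
  keep <- time <= upper_time
  time <- time[keep]; conc <- conc[keep]
  if (length(time) < 2) {
    stop("insufficient data: need >= 2 samples at or below upper_time",
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  total <- 0
  for (i in seq_len(length(time) - 1L)) {
    t1 <- time[i]; t2 <- time[i + 1L]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    dt <- t2 - t1
    logdown <- method == "linear_up_log_down" && c1 > c2 && c2 > 0
    if (moment == 0) {
      seg <- if (logdown) dt * (c1 - c2) / log(c1 / c2) else dt * (c1 + c2) / 2
    } else {
      # first moment: linear trapezoid of t*C; log-down segments use the
      # exact moment integral of the mono-exponential through the two points
      if (logdown) {
        k <- log(c1 / c2) / dt
        seg <- (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
      } else {
        seg <- dt * (t1 * c1 + t2 * c2) / 2
      }
    }
    total <- total + seg
  }
  total
}

#' Fit the terminal elimination rate constant
#'
#' Ordinary least squares of ln(conc) on time over candidate terminal
#' windows. \code{best_fit} evaluates every window of >= 3 terminal
#' quantifiable points (excluding the Tmax point for extravascular
#' profiles; Tmax is a valid candidate for iv bolus) and picks the one
#' with maximal adjusted R-squared, ties broken in favour of more
#' points.
#'
#' @param time,conc sample vectors; non-positive concentrations are
#'   excluded from fitting.
#' @param selection "best_fit" or "manual".
#' @param indices for \code{selection = "manual"}, indices (into the
#'   original vectors) of the points to regress on.
#' @param exclude_tmax drop the Tmax point from the candidate windows
#'   (extravascular convention).
#' @return list with \code{lambda_z} (1/h), \code{n_points},
#'   \code{adj_r2}, \code{intercept}, and \code{indices} used.
#' @export
fit_lambda_z <- function(time, conc, selection = c("best_fit", "manual"),
                         indices = NULL, exclude_tmax = TRUE) {
  selection <- match.arg(selection)
  usable <- which(conc > 0)
  if (selection == "manual") {
    idx <- intersect(indices, usable)
    if (length(idx) < 3) stop("insufficient data: need >= 3 positive points",
                              call. = FALSE)
    return(lz_ols(time[idx], conc[idx], idx))
  }
  itmax <- usable[which.max(conc[usable])]
  cand <- usable[usable >= itmax]
  if (exclude_tmax) cand <- setdiff(cand, itmax)
  n <- length(cand)
  if (n < 3) stop("insufficient data: need >= 3 quantifiable terminal points",
                  call. = FALSE)
  best <- NULL
  for (start in seq_len(n - 2L)) {
    idx <- cand[start:n]
    fit <- lz_ols(time[idx], conc[idx], idx)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$adj_r2 > best$adj_r2 + 1e-12 ||
        (abs(fit$adj_r2 - best$adj_r2) <= 1e-12 && fit$n_points > best$n_points)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("no terminal phase: all candidate slopes >= 0",
                          call. = FALSE)
  best
}

lz_ols <- function(t, c, idx) {
  y <- log(c)
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) return(NULL)
  n <- length(t)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(lambda_z = unname(-slope), n_points = n, adj_r2 = adj,
       intercept = unname(fit$coefficients[1]), indices = idx)
}

#' Run a full non-compartmental analysis on one profile
#'
#' Cmax/Tmax are read from the observed points (earliest time wins on
#' ties). AUC_last runs to the last quantifiable point;
#' AUC_inf = AUC_last + C_last/lambda_z; AUMC carries the matching
#' extrapolation terms; MRT = AUMC/AUC (absorption-inclusive for oral
#' profiles). CL = dose/AUC_inf and Vz = CL/lambda_z, apparent (per-F)
#' after oral dosing. For an iv bolus whose first record is a pre-dose
#' zero, C0 is back-extrapolated log-linearly from the first two
#' quantifiable points and the 0-to-first-sample segment added.
#'
#' @param profile a \code{\link{conc_profile}}.
#' @param method AUC method, see \code{\link{auc_trapezoid}}.
#' @param lambda_selection,lambda_indices passed to
#'   \code{\link{fit_lambda_z}}.
#' @return object of class \code{nca_result} (a named list).
#' @export
run_nca <- function(profile, method = c("linear_up_log_down", "linear"),
                    lambda_selection = "best_fit", lambda_indices = NULL) {
  method <- match.arg(method)
  if (!inherits(profile, "conc_profile")) stop("need a conc_profile", call. = FALSE)
  if (is.null(profile$dose)) stop("profile has no dose event", call. = FALSE)
  route <- profile$dose$route
  s <- profile$samples
  # BLQ handling: pre-Tmax BLQ -> 0; post-Tmax BLQ dropped
  conc <- ifelse(s$blq, 0, s$conc)
  itmax_raw <- which.max(conc)
  keep <- !(s$blq & seq_along(conc) > itmax_raw)
  time <- s$time[keep]; conc <- conc[keep]
  if (sum(conc > 0) < 2) stop("insufficient data: fewer than 2 quantifiable points",
                              call. = FALSE)

  # iv bolus back-extrapolation of C0 when no positive time-0 sample
  if (route == "iv_bolus" && !(time[1] == 0 && conc[1] > 0)) {
    pos <- which(conc > 0)
    i1 <- pos[1]; i2 <- if (length(pos) > 1) pos[2] else NA
    c0 <- if (!is.na(i2) && conc[i2] < conc[i1] && conc[i2] > 0) {
      exp(log(conc[i1]) - time[i1] *
            (log(conc[i2]) - log(conc[i1])) / (time[i2] - time[i1]))
    } else conc[i1]
    if (time[1] == 0) conc[1] <- c0 else { time <- c(0, time); conc <- c(c0, conc) }
  }

  ilast <- max(which(conc > 0))
  tq <- time[seq_len(ilast)]; cq <- conc[seq_len(ilast)]
  imax <- which.max(cq)
  cmax <- cq[imax]; tmax <- tq[imax]
  auc_last <- auc_trapezoid(tq, cq, method = method)
  aumc_last <- auc_trapezoid(tq, cq, method = method, moment = 1)

  lz <- fit_lambda_z(tq, cq, selection = lambda_selection,
                     indices = lambda_indices,
                     exclude_tmax = route != "iv_bolus")
  lambda_z <- lz$lambda_z
  c_last <- cq[ilast]; t_last <- tq[ilast]
  auc_inf <- auc_last + c_last / lambda_z
  aumc_inf <- aumc_last + c_last * t_last / lambda_z + c_last / lambda_z^2
  dose <- profile$dose$dose_per_bw
  cl <- 1000 * dose / auc_inf           # L/h/kg (apparent if oral)
  vz <- cl / lambda_z                   # L/kg

  structure(list(
    subject_id = profile$subject_id, species = profile$species,
    sex = profile$sex, matrix = profile$matrix, route = route, dose = dose,
    cmax = cmax, tmax = tmax, auc_last = auc_last, auc_inf = auc_inf,
    lambda_z = lambda_z, t_half = log(2) / lambda_z,
    mrt_last = aumc_last / auc_last, mrt_inf = aumc_inf / auc_inf,
    vz = vz, cl = cl, apparent = route == "oral",
    n_lambda_points = lz$n_points, adj_r2 = lz$adj_r2,
    extrapolated_fraction = (auc_inf - auc_last) / auc_inf
  ), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  flag <- if (x$apparent) "/F (apparent, oral)" else ""
  cat(sprintf(
    paste0("<nca_result> %s %s %s | Cmax %.4g ng/mL at %.3g h | ",
           "AUC_last %.4g, AUC_inf %.4g h*ng/mL | t1/2 %.3g h | ",
           "CL%s %.3g L/h/kg | Vz%s %.3g L/kg\n"),
    x$subject_id, x$species, x$route, x$cmax, x$tmax, x$auc_last,
    x$auc_inf, x$t_half, flag, x$cl, flag, x$vz))
  invisible(x)
}

#' Tabulate NCA results
#'
#' @param results list of \code{nca_result} objects.
#' @return data.frame, one row per result.
#' @export
nca_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(r[c("subject_id", "species", "sex", "matrix", "route", "dose",
                   "cmax", "tmax", "auc_last", "auc_inf", "lambda_z", "t_half",
                   "mrt_last", "mrt_inf", "vz", "cl", "apparent",
                   "n_lambda_points", "adj_r2", "extrapolated_fraction")],
               stringsAsFactors = FALSE)
  }))
}

#' Dose-group summary of NCA parameters
#'
#' Mean and SD per (species, sex, route, dose) group, mirroring the
#' usual mean +/- SD study-report layout; a Welch two-sample t-test
#' p-value between sexes is attached as a plain report field when both
#' sexes are present. SD is NA when n = 1.
#'
#' @param results list of \code{nca_result} objects (or the data.frame
#'   from \code{\link{nca_table}}).
#' @return data.frame in long format: group columns, parameter, n,
#'   mean, sd, p_sex.
#' @export
nca_group_summary <- function(results) {
  tab <- if (is.data.frame(results)) results else nca_table(results)
  pars <- c("cmax", "tmax", "auc_last", "auc_inf", "t_half",
            "mrt_last", "mrt_inf", "vz", "cl")
  groups <- unique(tab[, c("species", "route", "dose", "sex")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- tab[tab$species == g$species & tab$route == g$route &
                 tab$dose == g$dose & tab$sex == g$sex, ]
    other <- tab[tab$species == g$species & tab$route == g$route &
                   tab$dose == g$dose & tab$sex != g$sex, ]
    do.call(rbind, lapply(pars, function(p) {
      x <- sub[[p]]
      pval <- if (nrow(other) >= 2 && nrow(sub) >= 2 &&
                  stats::sd(x) > 0 && stats::sd(other[[p]]) > 0) {
        stats::t.test(x, other[[p]])$p.value
      } else NA_real_
      data.frame(species = g$species, route = g$route, dose = g$dose,
                 sex = g$sex, parameter = p, n = length(x), mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 p_sex = pval, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Absolute oral bioavailability from mean AUCs
#'
#' F\% = 100 * (AUC_po/dose_po) / (AUC_iv/dose_iv), computed from group
#' mean AUCs without statistical analysis. The default interval
#' convention is AUC to the last common sampling time (the reported
#' 0-12 h / 0-24 h windows), AUC_inf being selectable by passing those
#' means instead.
#'
#' @param mean_auc_po,mean_auc_iv group mean AUCs, h*ng/mL.
#' @param dose_po,dose_iv doses, mg/kg.
#' @return bioavailability in percent.
#' @examples
#' bioavailability(765, 10, 3217, 10)  # 23.8
#' @export
bioavailability <- function(mean_auc_po, dose_po, mean_auc_iv, dose_iv) {
  vals <- c(mean_auc_po, dose_po, mean_auc_iv, dose_iv)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all AUCs and doses must be positive", call. = FALSE)
  }
  100 * (mean_auc_po / dose_po) / (mean_auc_iv / dose_iv)
}

#' Dose-proportionality ratios
#'
#' Exposure values (Cmax or AUC) by ascending dose, normalized to the
#' lowest dose.
#'
#' @param values exposures ordered by ascending dose, all > 0.
#' @return numeric ratios, first element 1.
#' @examples
#' dose_proportionality(c(402, 2000, 6730))  # 1 : 4.98 : 16.74
#' @export
dose_proportionality <- function(values) {
  if (length(values) < 2) stop("need >= 2 dose levels", call. = FALSE)
  if (any(values <= 0)) stop("values must be > 0", call. = FALSE)
  values / values[1]
}

#' Accumulation ratio after repeated dosing
#'
#' Plain quotient of last-dose to first-dose exposure.
#'
#' @param value_last_dose,value_first_dose exposures (Cmax or AUC), > 0.
#' @return dimensionless ratio.
#' @examples
#' accumulation_ratio(1169, 2000)  # 0.58
#' @export
accumulation_ratio <- function(value_last_dose, value_first_dose) {
  if (value_first_dose <= 0 || value_last_dose <= 0) {
    stop("exposures must be > 0", call. = FALSE)
  }
  value_last_dose / value_first_dose
}
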