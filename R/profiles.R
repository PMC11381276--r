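#' Dosing event
#'
#' @param route "iv_bolus" or "oral".
#' @param dose_per_bw dose in mg per kg body weight; must be positive.
#' @param time dosing time in hours (default 0).
#' @param body_weight optional body weight in kg, needed only when
#'   absolute amounts are derived (excretion mass balance).
#' @return object of class \code{dose_event}.
#' @export
dose_event <- function(route, dose_per_bw, time = 0, body_weight = NULL) {
  route <- match.arg(route, c("iv_bolus", "oral"))
  stopifnot(is.numeric(dose_per_bw), length(dose_per_bw) == 1L)
  if (dose_per_bw <= 0) stop("dose_per_bw must be > 0", call. = FALSE)
  if (time < 0) stop("dose time must be >= 0", call. = FALSE)
  structure(list(route = route, dose_per_bw = dose_per_bw,
                 time = time, body_weight = body_weight),
            class = "dose_event")
}

#' Concentration-time profile for one subject and matrix
#'
#' Units are fixed pipeline-wide: time in hours, concentration in
#' ng/mL, dose in mg/kg. Samples must have strictly increasing times;
#' a pre-dose time-0 row is retained. Below-LLOQ handling follows the
#' usual NCA convention: pre-Tmax BLQ concentrations count as 0, BLQ
#' samples after Tmax are dropped from lambda-z fitting and from the
#' AUC beyond the last quantifiable point.
#'
#' @param subject_id subject identifier.
#' @param species one of mouse/rat/dog/monkey/human.
#' @param sex "male", "female" or "unspecified".
#' @param matrix matrix name ("plasma" or a tissue).
#' @param dose a \code{\link{dose_event}}.
#' @param time,conc numeric vectors of sampling times (h) and
#'   concentrations (ng/mL).
#' @param blq logical flag per sample; defaults to \code{conc < lloq}.
#' @param lloq lower limit of quantification in ng/mL.
#' @return object of class \code{conc_profile}.
#' @export
conc_profile <- function(subject_id, species, sex = "unspecified",
                         matrix = "plasma", dose, time, conc,
                         blq = NULL, lloq = 0) {
  species <- match.arg(species, c("mouse", "rat", "dog", "monkey", "human"))
  sex <- match.arg(sex, c("male", "female", "unspecified"))
  if (!inherits(dose, "dose_event")) stop("dose must be a dose_event", call. = FALSE)
  stopifnot(length(time) == length(conc))
  if (any(diff(time) <= 0)) {
    stop("sample times must be strictly increasing for subject ",
         subject_id, " / ", matrix, call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (is.null(blq)) blq <- conc < lloq
  structure(list(subject_id = as.character(subject_id), species = species,
                 sex = sex, matrix = matrix, dose = dose,
                 samples = data.frame(time = time, conc = conc, blq = blq),
                 lloq = lloq),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s %s %s %s | %s %.3g mg/kg | %d samples\n",
              x$subject_id, x$species, x$sex, x$matrix,
              x$dose$route, x$dose$dose_per_bw, nrow(x$samples)))
  invisible(x)
}

profile_csv_columns <- c("subject", "species", "sex", "matrix", "route",
                         "dose_mg_per_kg", "time_h", "conc_ng_ml")

#' Read concentration-time profiles from CSV
#'
#' Expects columns \code{subject, species, sex, matrix, route,
#' dose_mg_per_kg, time_h, conc_ng_ml} and optionally \code{blq},
#' \code{lloq}, \code{body_weight_kg}. One profile is created per
#' (subject, matrix) pair, samples sorted by time.
#'
#' @param path CSV file path.
#' @return list of \code{\link{conc_profile}} objects.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(profile_csv_columns, names(d))
  if (length(missing_cols)) {
    stop("profile CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"blq" %in% names(d)) d$blq <- NA
  if (!"lloq" %in% names(d)) d$lloq <- 0
  if (!"body_weight_kg" %in% names(d)) d$body_weight_kg <- NA_real_
  keys <- unique(d[, c("subject", "matrix")])
  lapply(seq_len(nrow(keys)), function(i) {
    g <- d[d$subject == keys$subject[i] & d$matrix == keys$matrix[i], ]
    g <- g[order(g$time_h), ]
    if (anyDuplicated(g$time_h)) {
      stop("duplicate sample times for subject ", keys$subject[i], " / ",
           keys$matrix[i], call. = FALSE)
    }
    bw <- g$body_weight_kg[1]
    conc_profile(
      subject_id = g$subject[1], species = g$species[1], sex = g$sex[1],
      matrix = g$matrix[1],
      dose = dose_event(g$route[1], g$dose_mg_per_kg[1],
                        body_weight = if (is.na(bw)) NULL else bw),
      time = g$time_h, conc = g$conc_ng_ml,
      blq = if (all(is.na(g$blq))) NULL else as.logical(g$blq),
      lloq = g$lloq[1]
    )
  })
}

#' Write concentration-time profiles to CSV
#'
#' Deterministic column order; round-trips through
#' \code{\link{read_profiles}}.
#'
#' @param profiles list of \code{\link{conc_profile}} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(subject = p$subject_id, species = p$species, sex = p$sex,
               matrix = p$matrix, route = p$dose$route,
               dose_mg_per_kg = p$dose$dose_per_bw,
               time_h = p$samples$time, conc_ng_ml = p$samples$conc,
               blq = p$samples$blq, lloq = p$lloq,
               body_weight_kg = if (is.null(p$dose$body_weight)) NA_real_
                                else p$dose$body_weight,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
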