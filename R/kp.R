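# Rodgers-Rowland tissue:plasma partition coefficients.
#
# For a moderate-to-strong base (pKa of the basic center >= 7) the
# tissue-to-unbound-plasma ratio is
#
#   Kpu = f_ew + X/Y * f_iw
#         + Ka_ap * AP * 10^(pKa - pH_iw) / Y
#         + (P * f_nl + (0.3 P + 0.7) * f_np) / Y
#
# with X = 1 + 10^(pKa - pH_iw), Y = 1 + 10^(pKa - pH_p), P = 10^logP,
# and the acidic-phospholipid association constant Ka_ap derived from
# the erythrocyte partitioning implied by the blood:plasma ratio:
#
#   Kpu_bc = (BP - 1 + Hct) / (Hct * fup)
#   Ka_ap  = (Kpu_bc - X_bc/Y * f_iw_bc - lipid term) *
#            Y / (AP_bc * 10^(pKa - pH_bc))
#
# Neutral compounds drop the ionization and association terms:
# Kpu = f_ew + f_iw + P*f_nl + (0.3P+0.7)*f_np. The reference side is
# unbound drug in plasma water, so Kp = fup * Kpu.

lipid_term <- function(p, f_nl, f_np) p * f_nl + (0.3 * p + 0.7) * f_np

ka_ap_from_blood <- function(logp, pka, fup, bp, hct,
                             comp = tissue_composition()) {
  bc <- comp[comp$tissue == "blood_cells", ]
  p <- 10^logp
  x_bc <- 1 + 10^(pka - pbpk_ph$blood_cells)
  y <- 1 + 10^(pka - pbpk_ph$plasma)
  kpu_bc <- (bp - 1 + hct) / (hct * fup)
  resid <- kpu_bc - (x_bc / y) * bc$f_iw - lipid_term(p, bc$f_nl, bc$f_np) / y
  if (resid <= 0) {
    warning("blood-cell partitioning leaves no room for acidic-phospholipid ",
            "association; Ka set to 0", call. = FALSE)
    return(0)
  }
  resid * y / (bc$ap * 10^(pka - pbpk_ph$blood_cells))
}

#' Tissue:plasma partition coefficient (Rodgers-Rowland)
#'
#' Mechanistic Kp prediction from tissue composition, pH partitioning
#' (plasma 7.4, intracellular 7.0), neutral lipid/phospholipid
#' partitioning driven by logP, and, for moderate-to-strong bases,
#' acidic-phospholipid association calibrated to the blood-cell
#' partitioning implied by the blood:plasma ratio. Deterministic given
#' (compound, species).
#'
#' @param compound a \code{\link{compound_card}}; a compound with
#'   \code{pka >= 7} uses the base equations, \code{pka = NA} the
#'   neutral equations.
#' @param organ tissue name present in \code{\link{tissue_composition}},
#'   or \code{"water"} for a hypothetical pure-water reference tissue.
#' @param fup fraction unbound in plasma for the species modelled.
#' @param bp blood:plasma concentration ratio (default 1, not measured
#'   for this compound).
#' @param hematocrit hematocrit fraction (default 0.45).
#' @return Kp (tissue:plasma), a positive scalar.
#' @export
rodgers_rowland_kp <- function(compound, organ, fup, bp = 1,
                               hematocrit = 0.45) {
  if (!is.numeric(fup) || fup <= 0) stop("fup must be > 0", call. = FALSE)
  comp <- tissue_composition()
  if (identical(organ, "water")) {
    row <- data.frame(f_ew = 1, f_iw = 0, f_nl = 0, f_np = 0, ap = 0)
  } else {
    row <- comp[comp$tissue == organ, ]
    if (nrow(row) == 0) {
      stop("no composition data for organ '", organ, "'", call. = FALSE)
    }
  }
  p <- 10^compound$logp
  is_base <- is.finite(compound$pka) && compound$pka >= 7
  if (is_base) {
    x <- 1 + 10^(compound$pka - pbpk_ph$intracellular)
    y <- 1 + 10^(compound$pka - pbpk_ph$plasma)
    ka <- ka_ap_from_blood(compound$logp, compound$pka, fup, bp, hematocrit)
    kpu <- row$f_ew + (x / y) * row$f_iw +
      ka * row$ap * 10^(compound$pka - pbpk_ph$intracellular) / y +
      lipid_term(p, row$f_nl, row$f_np) / y
  } else {
    kpu <- row$f_ew + row$f_iw + lipid_term(p, row$f_nl, row$f_np)
  }
  fup * kpu
}

#' Partition coefficients for all PBPK organs
#'
#' @inheritParams rodgers_rowland_kp
#' @return named numeric vector of Kp over the model's organs.
#' @export
kp_set <- function(compound, fup, bp = 1, hematocrit = 0.45) {
  kps <- vapply(pbpk_organs, function(org) {
    rodgers_rowland_kp(compound, org, fup = fup, bp = bp,
                       hematocrit = hematocrit)
  }, numeric(1))
  names(kps) <- pbpk_organs
  kps
}
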