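#' Compound property card
#'
#' Drug-specific physicochemical and in vitro parameters feeding the
#' IVIVE chain and the PBPK model.
#'
#' @param mw molecular weight, g/mol.
#' @param logp n-octanol/water log partition coefficient.
#' @param pka dissociation constant of the basic center; compounds with
#'   \code{pka >= 7} are treated as moderate-to-strong bases by the
#'   tissue-partitioning equations.
#' @param solubility aqueous solubility at pH 7.4, mg/L.
#' @param fup named numeric vector of fraction unbound in plasma per
#'   species (values in (0, 1]).
#' @param papp Caco-2 apparent permeability, cm/s.
#' @param clint_invitro microsomal intrinsic clearance, mL/min/mg
#'   protein (named per species where available).
#' @param fub_microsome fraction unbound in the microsomal incubation
#'   (default 1).
#' @return object of class \code{compound_card}.
#' @export
compound_card <- function(mw, logp, pka = NA_real_, solubility = NA_real_,
                          fup, papp = NA_real_, clint_invitro = NULL,
                          fub_microsome = 1) {
  if (mw <= 0) stop("mw must be > 0", call. = FALSE)
  if (any(fup <= 0 | fup > 1)) stop("fup must be in (0, 1]", call. = FALSE)
  if (fub_microsome < 0 || fub_microsome > 1)
    stop("fub_microsome must be in [0, 1]", call. = FALSE)
  structure(list(mw = mw, logp = logp, pka = pka, solubility = solubility,
                 fup = fup, papp = papp, clint_invitro = clint_invitro,
                 fub_microsome = fub_microsome),
            class = "compound_card")
}

#' Deg-AZM compound card
#'
#' Default property card for deglycosylated azithromycin: MW 433.59
#' g/mol, logP 1.7, basic pKa 9.0, solubility 3450 mg/L at pH 7.4,
#' Caco-2 Papp 3e-7 cm/s, microsomal intrinsic clearance 0.016
#' mL/min/mg (rat), fraction unbound in plasma 0.61 (rat) and 0.27
#' (human), microsomal binding taken as complete (fub = 1).
#'
#' @return a \code{\link{compound_card}}.
#' @export
deg_azm_card <- function() {
  compound_card(
    mw = 433.59, logp = 1.7, pka = 9.0, solubility = 3450,
    fup = c(mouse = 1 - 0.493, rat = 0.61, dog = 1 - 0.874, human = 0.27),
    papp = 3e-7,
    clint_invitro = c(rat = 0.016),
    fub_microsome = 1
  )
}
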