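# Species physiology for the whole-body PBPK model.
#
# Organ volumes, regional blood flows, GFR and hematocrit are compiled
# from standard physiological reference tables for laboratory species
# and humans. Flows are stated per kg body weight; the liver inflow
# (hepatic artery + portal drainage from gut, spleen and stomach) is
# constrained to equal the hepatic blood flow used by the IVIVE chain
# (rat 55.2, human 20.7 mL/min/kg) so that the simulator and the
# well-stirred scaling share one hepatic flow. Tissue composition
# fractions (extracellular/intracellular water, neutral lipid, neutral
# phospholipid, acidic phospholipid) are the standard compilation used
# by tissue-composition partitioning methods.

pbpk_organs <- c("lung", "brain", "heart", "muscle", "adipose", "skin",
                 "bone", "gut", "spleen", "stomach", "liver", "kidney",
                 "gonads", "rest")

portal_organs <- c("gut", "spleen", "stomach")

#' Species physiology for the PBPK model
#'
#' @param species "rat" or "human".
#' @param body_weight body weight in kg; defaults to 0.25 (rat) or 60
#'   (human, a healthy Asian adult reference).
#' @return object of class \code{species_physiology}: body weight,
#'   hematocrit, GFR (mL/min/kg), cardiac output (mL/min/kg), and a
#'   per-organ table of volumes (L/kg) and blood flows (mL/min/kg),
#'   plus arterial/venous blood volumes.
#' @export
species_physiology <- function(species = c("rat", "human"),
                               body_weight = NULL) {
  species <- match.arg(species)
  if (species == "rat") {
    if (is.null(body_weight)) body_weight <- 0.25
    vol <- c(lung = 0.005, brain = 0.0057, heart = 0.0033, muscle = 0.404,
             adipose = 0.070, skin = 0.190, bone = 0.073, gut = 0.027,
             spleen = 0.002, stomach = 0.0046, liver = 0.0366,
             kidney = 0.0073, gonads = 0.0025, rest = 0.025)
    flow <- c(brain = 6, heart = 15, muscle = 83, adipose = 21, skin = 17,
              bone = 37, kidney = 42, gonads = 1.5, gut = 40, spleen = 3.5,
              stomach = 4.5, rest = 22.3)
    hepatic_artery <- 7.2            # liver inflow totals 55.2 mL/min/kg
    blood_volume <- 0.074
    hct <- 0.46
    gfr <- 5.2
  } else {
    if (is.null(body_weight)) body_weight <- 60
    vol <- c(lung = 0.0076, brain = 0.020, heart = 0.0047, muscle = 0.40,
             adipose = 0.19, skin = 0.037, bone = 0.086, gut = 0.0171,
             spleen = 0.0026, stomach = 0.0021, liver = 0.026,
             kidney = 0.0044, gonads = 0.0005, rest = 0.030)
    flow <- c(brain = 10, heart = 3.3, muscle = 14, adipose = 4.3,
              skin = 4.2, bone = 4.2, kidney = 15.7, gonads = 0.04,
              gut = 13, spleen = 2.5, stomach = 1.0, rest = 6.56)
    hepatic_artery <- 4.2            # liver inflow totals 20.7 mL/min/kg
    blood_volume <- 0.074
    hct <- 0.45
    gfr <- 1.8
  }
  co <- sum(flow) + hepatic_artery   # lung flow = cardiac output
  q_liver_in <- hepatic_artery + sum(flow[portal_organs])
  organs <- data.frame(
    organ = pbpk_organs,
    volume = as.numeric(vol[pbpk_organs]),
    flow = as.numeric(c(lung = co, flow, liver = q_liver_in)[pbpk_organs]),
    stringsAsFactors = FALSE
  )
  structure(list(
    species = species, body_weight = body_weight, hematocrit = hct,
    gfr = gfr, cardiac_output = co, hepatic_artery = hepatic_artery,
    organs = organs,
    arterial_volume = blood_volume / 3,
    venous_volume = blood_volume * 2 / 3
  ), class = "species_physiology")
}

#' Tissue composition table for partition-coefficient prediction
#'
#' Fractional tissue composition: extracellular water (f_ew),
#' intracellular water (f_iw), neutral lipids (f_nl), neutral
#' phospholipids (f_np), and acidic phospholipid concentration (ap,
#' mg/g tissue). The \code{blood_cells} row carries the erythrocyte
#' composition used to back-calculate the acidic-phospholipid
#' association constant of basic drugs; \code{stomach} shares the gut
#' wall composition, \code{rest} the muscle composition.
#'
#' @return data.frame keyed by \code{tissue}.
#' @export
tissue_composition <- function() {
  comp <- data.frame(
    tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney",
               "liver", "lung", "muscle", "skin", "spleen", "gonads",
               "stomach", "rest", "blood_cells"),
    f_ew = c(0.135, 0.100, 0.162, 0.282, 0.320, 0.273, 0.161, 0.336,
             0.118, 0.382, 0.207, 0.255, 0.282, 0.118, 0),
    f_iw = c(0.017, 0.346, 0.620, 0.475, 0.456, 0.483, 0.573, 0.446,
             0.630, 0.291, 0.579, 0.525, 0.475, 0.630, 0.603),
    f_nl = c(0.853, 0.017, 0.039, 0.038, 0.014, 0.012, 0.014, 0.022,
             0.010, 0.060, 0.0077, 0.0033, 0.038, 0.010, 0.0017),
    f_np = c(0.0016, 0.0017, 0.0015, 0.0125, 0.0111, 0.0242, 0.0240,
             0.0128, 0.0072, 0.0044, 0.0113, 0.0066, 0.0125, 0.0072,
             0.0029),
    ap = c(0.40, 0.67, 0.40, 2.41, 2.25, 5.03, 4.56, 3.91, 1.53, 1.32,
           3.18, 2.00, 2.41, 1.53, 0.5),
    stringsAsFactors = FALSE
  )
  comp
}

# intracellular, blood-cell and plasma pH used by the partitioning
# equations
pbpk_ph <- list(plasma = 7.4, intracellular = 7.0, blood_cells = 7.22)
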