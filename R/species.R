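#' Species scaling constants for microsomal IVIVE
#'
#' Registry of the physiological constants used to scale intrinsic
#' clearance measured in liver microsomes up to the whole body:
#' microsomal protein per gram liver (MPPGL), liver weight per kg body
#' weight, and hepatic blood flow. The scaling factor SF is their
#' product, MPPGL x liver/body-weight ratio, in mg microsomal protein
#' per kg body weight.
#'
#' @return data.frame with one row per species and columns
#'   \code{species}, \code{mppgl} (mg/g), \code{liver_bw_ratio} (g/kg),
#'   \code{q_h} (mL/min/kg), \code{sf} (mg/kg).
#' @export
species_table <- function() {
  tab <- data.frame(
    species        = c("mouse", "rat", "dog", "monkey", "human"),
    mppgl          = c(45,     44.8,  77.9,  45,       48.8),
    liver_bw_ratio = c(87.5,   40.0,  32.0,  32.5,     25.7),
    q_h            = c(90,     55.2,  30.9,  44,       20.7),
    stringsAsFactors = FALSE
  )
  tab$sf <- tab$mppgl * tab$liver_bw_ratio
  tab
}

#' Look up the scaling constants for one species
#'
#' @param species one of \code{"mouse"}, \code{"rat"}, \code{"dog"},
#'   \code{"monkey"}, \code{"human"}.
#' @return a one-row list with fields \code{species}, \code{mppgl},
#'   \code{liver_bw_ratio}, \code{q_h} and \code{sf}.
#' @examples
#' species_constants("human")$sf  # 48.8 * 25.7 = 1254.16 mg/kg
#' @export
species_constants <- function(species) {
  tab <- species_table()
  i <- match(species, tab$species)
  if (is.na(i)) {
    stop("unknown species '", species, "'; supported: ",
         paste(tab$species, collapse = ", "), call. = FALSE)
  }
  as.list(tab[i, ])
}
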