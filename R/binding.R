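# Equilibrium dialysis plasma-protein binding.

#' Percent bound from an equilibrium dialysis pair
#'
#' Bound\% = 100 * (C_total - C_free) / C_total, where C_total is the
#' plasma-side and C_free the buffer-side concentration. A buffer-side
#' concentration exceeding the plasma side yields a negative percentage
#' which is returned with a warning rather than clipped.
#'
#' @param c_total plasma-side concentration (> 0).
#' @param c_free buffer-side concentration (>= 0).
#' @return percent bound.
#' @examples
#' bound_percent(100, 13.5)  # 86.5
#' @export
bound_percent <- function(c_total, c_free) {
  if (any(c_total <= 0)) stop("c_total must be > 0", call. = FALSE)
  if (any(c_free < 0)) stop("c_free must be >= 0", call. = FALSE)
  if (any(c_free > c_total)) {
    warning("c_free exceeds c_total: negative bound% returned", call. = FALSE)
  }
  100 * (c_total - c_free) / c_total
}

#' Summarise dialysis measurements into binding rates and fup
#'
#' Replicates are averaged within each nominal concentration level; the
#' across-level average is the unweighted mean of level means (matching
#' the usual three-level study layout), and the fraction unbound in
#' plasma is fup = 1 - average/100.
#'
#' @param measurements data.frame with columns \code{species},
#'   \code{nominal_conc}, \code{c_total}, \code{c_free} (one row per
#'   replicate).
#' @return list with \code{levels} (per-level mean/SD of bound\%),
#'   \code{by_species} (across-level average, SD of level means, fup).
#' @export
binding_summary <- function(measurements) {
  req <- c("species", "nominal_conc", "c_total", "c_free")
  if (!all(req %in% names(measurements))) {
    stop("measurements need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(measurements) == 0) stop("no dialysis measurements", call. = FALSE)
  measurements$bound <- bound_percent(measurements$c_total, measurements$c_free)
  key <- interaction(measurements$species, measurements$nominal_conc, drop = TRUE)
  levels_df <- do.call(rbind, lapply(split(measurements, key), function(g) {
    data.frame(species = g$species[1], nominal_conc = g$nominal_conc[1],
               n = nrow(g), bound_mean = mean(g$bound),
               bound_sd = if (nrow(g) > 1) stats::sd(g$bound) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  levels_df <- levels_df[order(levels_df$species, levels_df$nominal_conc), ]
  rownames(levels_df) <- NULL
  by_species <- do.call(rbind, lapply(split(levels_df, levels_df$species),
                                      function(g) {
    avg <- mean(g$bound_mean)
    data.frame(species = g$species[1], n_levels = nrow(g), bound_avg = avg,
               bound_sd = if (nrow(g) > 1) stats::sd(g$bound_mean) else NA_real_,
               fup = 1 - avg / 100, stringsAsFactors = FALSE)
  }))
  rownames(by_species) <- NULL
  list(levels = levels_df, by_species = by_species)
}
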