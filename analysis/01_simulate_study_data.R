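#!/usr/bin/env Rscript
# Generate the synthetic study inputs every downstream step consumes:
# rat iv/oral concentration-time profiles on the study sampling
# schedules, microsomal stability assays, equilibrium dialysis
# measurements, and interval excretion records. All seeded, all written
# as plain CSV under results/synthetic/.

suppressPackageStartupMessages(library(degpk))
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)

seed <- 20240801

# rat disposition roughly matching the observed study: CL ~3 L/h/kg,
# V ~4.9 L/kg iv; oral doses with F ~0.4 and fast absorption
iv <- generate_profiles(6, "iv_bolus", 10, pars = list(CL = 3.0, V = 4.9),
                        sigma = 0.15, bsv_cv = 0.2, lloq = 1,
                        id_prefix = "IV10-", seed = seed, sex = "male")
oral <- unlist(lapply(c(10, 25, 50), function(d) {
  generate_profiles(6, "oral", d,
                    pars = list(CL = 3.0, V = 4.9, ka = 5, F = 0.4),
                    sigma = 0.15, bsv_cv = 0.2, lloq = 1,
                    id_prefix = sprintf("PO%d-", d), seed = seed + d, sex = "male")
}), recursive = FALSE)
write_profiles(c(iv, oral), "results/synthetic/rat_profiles.csv")
cat("wrote", length(iv) + length(oral), "rat profiles (iv 10; po 10/25/50 mg/kg)\n")

# microsomal stability per species at the reported rate constants
ms <- do.call(rbind, lapply(
  c(mouse = 0.00360, rat = 0.0161, dog = 0.00180, human = 0.0149),
  function(ke) generate_microsomal_assay(ke, sigma = 0.04,
                                         n_replicates = 2, seed = seed)))
ms$species <- rep(c("mouse", "rat", "dog", "human"), each = 12)
monkey <- generate_microsomal_assay(0.0887, sigma = 0.04,
                                    schedule = c(0, 3, 6, 9, 15, 30),
                                    n_replicates = 2, seed = seed)
monkey$species <- "monkey"
write.csv(rbind(ms, monkey), "results/synthetic/microsomes.csv",
          row.names = FALSE)

# dialysis at the three nominal levels, species-typical binding
dia <- do.call(rbind, lapply(
  c(mouse = 49.3, rat = 39.2, dog = 87.4, human = 73.3),
  function(b) generate_dialysis(b, sigma = 0.03, seed = seed)))
dia$species <- rep(c("mouse", "rat", "dog", "human"), each = 9)
write.csv(dia, "results/synthetic/dialysis.csv", row.names = FALSE)

# excretion at the observed male fractions
exc <- generate_excretion(c(urine = 0.173, bile = 0.00752, feces = 0.0197),
                          k_elim = 0.35, dose_event("oral", 25),
                          body_weight = 0.25, sigma = 0.08, seed = seed)
write.csv(exc, "results/synthetic/excretion.csv", row.names = FALSE)

cat("synthetic inputs written under results/synthetic/\n")
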