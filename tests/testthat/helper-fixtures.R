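# shared fixtures: closed-form profiles and model organ names

one_cmt_iv <- function(dose = 10, v = 3, k = 0.66,
                       times = seq(0, 12, length.out = 200)) {
  conc_profile("sim", "rat", dose = dose_event("iv_bolus", dose),
               time = times, conc = 1000 * dose / v * exp(-k * times))
}

model_organs <- c("lung", "brain", "heart", "muscle", "adipose", "skin",
                  "bone", "gut", "spleen", "stomach", "liver", "kidney",
                  "gonads", "rest")

uniform_kp <- function(value = 1) stats::setNames(rep(value, 14), model_organs)

scaled_flow_physiology <- function(scale, species = "rat") {
  phys <- species_physiology(species)
  phys$organs$flow <- phys$organs$flow * scale
  phys$cardiac_output <- phys$cardiac_output * scale
  phys$hepatic_artery <- phys$hepatic_artery * scale
  phys
}
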