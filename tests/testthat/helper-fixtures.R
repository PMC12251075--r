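# Shared small fixtures; everything is generated in code.

fix_geometry <- function() flow_cell_geometry()          # 10 mm / 26 uL

fix_dyes <- function(cross_fraction = 0.01) default_dyes(cross_fraction)

fix_detector <- function(sd = 0, seed = NULL) {
  detector_config(relative_noise_sd = sd, rng_seed = seed)
}

# Noiseless single-exponential generator used by the calibration tests:
# I/I0 = a * 10^(-b * C) + c
gen_exponential <- function(conc, a = 1, b = 0.04, c = 0) {
  a * 10^(-b * conc) + c
}
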