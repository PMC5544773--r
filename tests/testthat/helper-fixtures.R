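# Shared synthetic ground truth, built once per test run.
pw_fix <- make_pseudo_water()

measured_axis <- function(step = 4, lo = 600, hi = 6000) {
  spectral_axis(seq(lo, hi, by = step), "wavenumber")
}

water_index_on <- function(axis) model_complex_index(pw_fix$model, axis)

# Forward-simulated water absorbance for the reference geometry
# (collimated 45 deg beam, ZnSe-like element, N = 10).
simulate_water <- function(axis, config = atr_config()) {
  simulate_atr_absorbance(water_index_on(axis), config)
}
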