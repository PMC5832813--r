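# Default pipeline configuration.
#
# Constants: Boltzmann's constant is fixed; the activation energy is the
# standard metabolic-theory value for ectotherm respiration; the energy
# density converts body mass (mg AFDW) to energy equivalents; the
# reference temperature is the flume experimental temperature.
constants:
  boltzmann_k_ev_per_k: 8.617e-5
  activation_energy_ev: 0.65
  energy_density_j_per_mg: 21.5
  reference_temperature_c: 18

# Defaunated-control resuspension (g m-2), global mean across flumes.
control:
  mode: global_mean
  value_g_m2: 32.25
  ci95: 1.73

# Individual metabolic-rate model. The allometric normalization is
# calibrated against the packaged flume dataset (mW at 1 mg AFDW).
metabolic_model:
  form: allometric
  a: 0.011
  b: 0.75

# Size (shell length mm, or wet weight mg for A. marina) to body mass
# (mg AFDW) power laws, M = p * size^q. The institute-specific
# coefficients behind the packaged dataset are unpublished; these are
# synthetic placeholders calibrated to the dataset's (size, mass) pairs.
conversion_rules:
  A. marina:        {p: 0.08170, q: 1.044}
  A. alba:          {p: 0.005123, q: 3.0}
  L. balthica:      {p: 0.010068, q: 3.0}
  S. plana:         {p: 0.014690, q: 2.625}
  R. philippinarum: {p: 0.010211, q: 3.0}
  C. edule:         {p: 0.006110, q: 3.236}

# Temperature scenarios for the Boltzmann-Arrhenius projection.
scenarios:
  - {label: winter, t_target_c: 7.2}
  - {label: plus3C_warming, t_target_c: 21}
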