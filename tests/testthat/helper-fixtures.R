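# Shared fixtures: generative truths used across test files.

# Nuisance baselines typical of an F350/330 unfolding transition.
nuisance_unfolding <- function(c_U50, temperature_C) {
  unfolding_params(alpha_F = 0.85, beta_F = 5e-4,
                   alpha_U = 1.05, beta_U = 2e-3,
                   m_folding = 1500, c_U50 = c_U50,
                   temperature_C = temperature_C)
}

default_grid <- seq(0, 45, by = 2.5)   # 19 points

raw_unfolding_signal <- function(p, cc) {
  # direct transcription of the extended two-state formula (independent of
  # the package's stable-branch evaluation); valid at moderate exponents
  E <- exp(p$m_folding / (8.314 * (p$temperature_C + 273.15)) *
             (cc - p$c_U50))
  (p$alpha_F + p$beta_F * cc + (p$alpha_U + p$beta_U * cc) * E) / (1 + E)
}
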