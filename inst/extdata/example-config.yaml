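# Example run configuration for the rpcompass command-line driver.
# Angles may be given in radians (theta_rad) or degrees (theta_deg).
model:
  B0_uT: 46
  theta_deg: 0
  A_per_nucleus_Lambda: [3, 3, 5]
  k_per_s: 1.0e+4
sweep:
  n_theta: 31
noise:
  vertical_rates_in_k: [0.01, 0.1, 1]
  parallel_rates_in_k: [0.1, 1, 10, 100]
  rates_in_k: [0, 0.1, 1, 10]
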