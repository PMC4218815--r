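# Example pipeline configuration: simulate the default study and analyze it.
sim:
  n_genes_per_species: 600
  probes_per_set: 11
  frac_de_human: 0.10
  frac_de_mouse: 0.10
  frac_xhyb_probes: 0.10
  xhyb_coupling: 0.5
  mixing_fraction_B: 0.5
  noise_sd: 0.25
  seed: 1
l_min: 15
i_min: 0.75
min_probes_per_set: 3
normalization: scale
alpha: 0.05
theta: 0.30
p_max: 0.05
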