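backend: izhikevich
n_neurons: 225.0
duration: 7.0
dt: 0.1
dl: 0.1
jitter_sd: 0.1
record_dt: 0.001
neuron:
  a: 0.02
  b: 0.2
  c_reset: -50.0
  d: 0.7
  drive: 5.0
  drive_sd: 0.05
  spike_cut: 30.0
  stim_weight: 50.0
gate:
  alpha_s: 0.1
  beta_s: 0.05
  theta_s: 0.2
  sigma_s: 0.02
coupling:
  backend: izhikevich
  g_bar_s: 0.2
  v_rev_syn: -0.8
  sigma_g: 0.5
  c_n: 2.1765
  kernel: gaussian
noise:
  D_noise: 1.0e-05
  tau_noise: 5.0
seeds:
  lattice: 1
  init: 51
  noise: 101
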