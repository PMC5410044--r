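model: builtin
simulate:
  profile:
    ref: 0.2
    X1: 0.6
    X2: 0.2
  n_pairs: 3000
  n_samples: 6
  five_prime_depletion: 0.3
  depth_jitter: 0.1
params:
  n_perm: 2000
seed: 20
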