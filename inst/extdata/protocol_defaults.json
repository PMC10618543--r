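{
  "mu_B": 4.16e-3,
  "b": 2.8e6,
  "N": 6,
  "tau": 1.68e2,
  "H_m": 1.84e9
}
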