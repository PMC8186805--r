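# Example optical-property override (values replace the shipped 690 nm
# defaults for the tissues named here; see read_media_table()).
GM:
  mu_a: 0.018
  mu_s: 7.8
  g: 0.89
  n: 1.37
skull:
  mu_a: 0.011
  mu_s: 91
  g: 0.99
  n: 1.37
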