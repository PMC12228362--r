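# Alternative allele-frequency calibration reading the published
# percentages literally as printed (BA1 0.001%, BS1 0.0001%), i.e.
# fractions 1e-5 / 1e-6. Apply via load_scheme(..., overrides_file =).
thresholds:
  ba1_af: 1.0e-05
  bs1_af: 1.0e-06
  pm2_af: 1.0e-07
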