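# Six-bile-salt + lecithin mixed micellar mobile phase (17 mM bile-salt stock,
# 0.75 mM lecithin, 0.15 M NaCl, 10 mM HEPES pH 6.5). Component CMCs are the
# literature values for the pure bile salts in 0.15 M NaCl; their unweighted
# mean (0.0046 M) is the mixture CMC used to convert total concentration to
# micellar concentration.
components:
  - {name: NaTC,  conc_mM: 2.71, cmc_M: 0.0040}
  - {name: NaTDC, conc_mM: 2.00, cmc_M: 0.0024}
  - {name: NaDC,  conc_mM: 2.08, cmc_M: 0.0024}
  - {name: NaC,   conc_mM: 2.08, cmc_M: 0.0075}
  - {name: NaGC,  conc_mM: 4.70, cmc_M: 0.0090}
  - {name: NaGDC, conc_mM: 3.43, cmc_M: 0.0022}
lecithin_mM: 0.75
nacl_M: 0.15
ph: 6.5
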