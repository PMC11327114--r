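# Minimal pipeline configuration: a 15 x 15 km synthetic study system,
# a short fit, and the sustainability scenario.
seed: 5
lattice: {n_rows: 15, n_cols: 15}
years: {from: 2010, to: 2020}
model: {n_chains: 2, n_iter: 2000}
scenarios:
  - {ssp: SSP1, rcm: historical-trend}
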