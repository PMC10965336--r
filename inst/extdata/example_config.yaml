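# Example pipeline configuration: a reduced five-year design.
seed: 42
window:
  start: 157
  end: 238
community:
  years: [2000, 2001, 2002, 2003, 2004]
  plots: 2
  traps_per_plot: 2
nests:
  nests_per_year: 10
trends:
  n_boot: 1000
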