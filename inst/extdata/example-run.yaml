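# Example spraytrack run configuration (synthetic season).
seed: 1
n_sim: 10000
min_len: 10
arima:
  p_max: 3
  d_max: 1
  q_max: 3
min_segment_frac: 0.15
max_breaks: 3
synthetic:
  n_traps_treated: 24
  n_traps_untreated: 19
  n_collections: 36
  site_effect: -1.7
  treatment_effect: 0.3
  divergence_index: 15
  seed: 20130617
# To analyse real data instead, drop the `synthetic:` block and give:
# trap_file: traps.csv
# cage_file: cages.csv
# weather_file: weather.csv
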