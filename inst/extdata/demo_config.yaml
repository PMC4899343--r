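# Demonstration pipeline configuration: a reduced synthetic cohort that
# runs end to end in a few seconds. Omitted keys keep package defaults.
seed: 1
cohort:
  n_case: 6
  n_control: 6
  n_peaks_total: 40
  grid_end: 10000
ga:
  population: 20
  generations: 10
screening:
  alpha: 0.05
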