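# Desk-scale demonstration configuration: full stage chain on a small
# simulated cohort with the wavelet grid restricted to the alpha band.
seed: 7
sim:
  n_subjects: 6
  trials_retained: [8, 12]
wavelet:
  f_min: 7.98
  f_max: 11.78
  f_step: 0.38
n_perm: 500
iterations: 10000
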