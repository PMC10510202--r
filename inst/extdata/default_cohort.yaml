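means:
  healthy:
  - 84.2
  - 79.23
  - 0.343
  - 0.31
  alcohol_use:
  - 81.6
  - 76.35
  - 0.341
  - 0.291
  tobacco_use:
  - 90.96
  - 87.3
  - 0.376
  - 0.318
  anxiety:
  - 95.76
  - 88.75
  - 0.35
  - 0.289
  depression:
  - 81.11
  - 78.3
  - 0.327
  - 0.299
sds:
  healthy:
  - 14.48
  - 13.11
  - 0.059
  - 0.052
  alcohol_use:
  - 13.66
  - 12.43
  - 0.064
  - 0.057
  tobacco_use:
  - 15.52
  - 17.74
  - 0.098
  - 0.087
  anxiety:
  - 15.9
  - 13.44
  - 0.082
  - 0.062
  depression:
  - 17.17
  - 17.25
  - 0.08
  - 0.07
group_n:
  healthy: 31
  alcohol_use: 87
  tobacco_use: 31
  anxiety: 25
  depression: 21
sex_n:
  male: 106
  female: 89
rmt_mean: 50.46
rmt_sd: 8.91
rmt_bounds:
- 31.0
- 78.0
templates:
  MNI152:
  - 78.16
  - 80.14
  - 0.293
  - 0.294
  Ernie:
  - 81.46
  - 72.58
  - 0.286
  - 0.244
mode: direct
latent_loading: 0.5
stim_multiplier: 1.2
max_didt: 1.5e+08
tes_current_mA: 2.0
seed: 1
protocols:
- motor_TMS
- prefrontal_TMS
- motor_tES
- prefrontal_tES
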