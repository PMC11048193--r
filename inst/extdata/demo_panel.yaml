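Chlorophyta:
  label: Chlorophyta
  mean_stokes:
  - 6.0
  - 0.45
  - 0.15
  - 0.05
  stokes_dispersion:
  - 0.25
  - 0.04
  - 0.04
  - 0.03
  shape:
    width_mean: 70.0
    width_sd: 18.0
    asymmetry: 0.3
    flatness: 2.0
  fluorescence_level: 0.6
  fluorescence_dispersion: 0.12
Bacillariophyta:
  label: Bacillariophyta
  mean_stokes:
  - 9.0
  - 0.1
  - 0.4
  - 0.1
  stokes_dispersion:
  - 0.25
  - 0.04
  - 0.04
  - 0.03
  shape:
    width_mean: 90.0
    width_sd: 22.0
    asymmetry: 0.0
    flatness: 4.0
  fluorescence_level: 0.45
  fluorescence_dispersion: 0.12
Cyanophyta:
  label: Cyanophyta
  mean_stokes:
  - 4.0
  - 0.3
  - -0.2
  - 0.15
  stokes_dispersion:
  - 0.25
  - 0.04
  - 0.04
  - 0.03
  shape:
    width_mean: 50.0
    width_sd: 12.0
    asymmetry: 0.5
    flatness: 1.2
  fluorescence_level: 1.0
  fluorescence_dispersion: 0.15
other_SPM:
  label: other_SPM
  mean_stokes:
  - 12.0
  - 0.65
  - 0.05
  - -0.05
  stokes_dispersion:
  - 0.35
  - 0.05
  - 0.05
  - 0.04
  shape:
    width_mean: 40.0
    width_sd: 15.0
    asymmetry: 0.0
    flatness: 2.5
  fluorescence_level: 0.05
  fluorescence_dispersion: 0.3
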