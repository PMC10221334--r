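# Population pharmacokinetic parameterizations and sampling schedules for
# the three study drugs. Units: min, mL, mL/min, 1/min, ug.
# Doses are package defaults (label strengths); all downstream ratio-scale
# quantities are dose-invariant under these linear models.
drugs:
  hydrochlorothiazide:
    model_kind: two_compartment_oral_lag
    dose_ug: 25000            # 25 mg
    Tlag_min: 24.24
    Ka_per_min: 0.01288
    ClF_mL_min: 575
    QF_mL_min: 423.33
    V1F_mL: 137000
    V2F_mL: 146000
    sampling_times_min: [0, 10, 20, 40, 60, 90, 120, 180, 240, 360, 480, 720, 960, 1440]
  donepezil:
    model_kind: one_compartment_oral
    dose_ug: 10000            # 10 mg
    Ka_per_min: 0.02167
    ClF_mL_min: 143.33
    V1F_mL: 391000
    sampling_times_min: [0, 30, 60, 90, 120, 150, 180, 210, 240, 360, 480, 720, 1080, 1440, 2160, 2880, 4320]
  amlodipine:
    model_kind: one_compartment_oral
    dose_ug: 10000            # 10 mg
    Ka_per_min: 0.01417
    ClF_mL_min: 370
    V1F_mL: 1300              # printed value; inconsistent with 40-50 h half-life
    V1F_mL_corrected: 1300000 # 1,300 L, reproduces the literature half-life
    sampling_times_min: [0, 60, 120, 240, 300, 360, 420, 480, 600, 720, 960, 1440, 2880, 4320]
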