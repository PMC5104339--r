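# Typical TFV chain: plasma tenofovir -> intracellular TFV-DP -> dATP/dGTP.
# Time in days, volumes in L, clearances in L/day, dose in ug TFV equivalents
# (one TDF 300 mg tablet contains 136 mg TFV), concentrations in ng/mL
# (plasma) or fmol per 10^6 PBMC (intracellular).
analyte: TFV
dose_ug: 136000
plasma:
  Ka: 80.1
  Vc_F: 390
  CL_F: 1410
  Vp_F: 877
  Q_F: 5390
ic:
  Kf: 1.4
  SC50: 6.55
  Kel: 0.228
  R: 0.0582          # recycling fraction (table-style percent: 5.82%)
dntp:
  dATP:
    R0: 155
    EC50: 1020
  dGTP:
    R0: 245
    EC50: 54.6
    gamma: 0.928     # time-waning exponent of the inhibition
variability:
  omega2:            # between-subject variances, exponential scale
    Vc_F: 0.288
    CL_F: 0.117
    Q_F: 0.0693
    Kf: 0.238
    Kel: 0.316
    R0_dATP: 0.220
    EC50_dATP: 1.70
    R0_dGTP: 0.203
  sigma2:            # residual variances per observation stream
    plasma: 0.0745
    ic: 0.115
    dATP: 0.258
    dGTP: 0.267
  error_model:
    plasma: exponential
    ic: proportional
    dATP: exponential
    dGTP: exponential
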