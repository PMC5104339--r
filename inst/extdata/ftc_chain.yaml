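# Typical FTC chain: plasma emtricitabine -> intracellular FTC-TP -> dCTP/TTP.
# Same unit conventions as the TFV chain; dose in ug FTC (200 mg tablet).
# Covariates: males have a larger plasma central volume
# (Vc/F = 99.4 + 24.3 * sex) and HIV-positive subjects a faster FTC-TP
# formation rate (Kf = 41.6 + 31.3 * hiv).
analyte: FTC
dose_ug: 200000
plasma:
  Ka: 55.7
  Vc_F: 99.4
  CL_F: 482
  Vp_F: 166
  Q_F: 141
ic:
  Kf: 41.6
  SC50: 3320
  Kel: 1.6
  R: 0.16
dntp:
  dCTP:
    R0: 771
    EC50: 44400
  TTP:
    R0: 335
    EC50: 18800
covariates:
  sex:
    block: plasma
    field: Vc_F
    coef: 24.3
  hiv:
    block: ic
    field: Kf
    coef: 31.3
variability:
  omega2:
    Vc_F: 0.0319
    CL_F: 0.0942
    Vp_F: 0.0335
    Kf: 0.0358
    Kel: 0.0561
    R0_dCTP: 0.195
    EC50_dCTP: 0.68
    R0_TTP: 0.383
    EC50_TTP: 1.02
  sigma2:
    plasma: 0.122
    ic: 0.0942
    dCTP: 0.229
    TTP: 0.356
  error_model:
    plasma: exponential
    ic: proportional
    dCTP: exponential
    TTP: exponential
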