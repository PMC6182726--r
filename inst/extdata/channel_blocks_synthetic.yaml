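# SYNTHETIC example channel-block specification.
# IC50 (uM) and Hill coefficients for the parent drug (AT) and its
# metabolite (NT) on the main ventricular currents. These are
# illustrative values in the range reported for tricyclic
# antidepressants in public patch-clamp literature, NOT measured
# potencies for these analytes; replace with assay data for real use.
AT:
  IKr:
    ic50_uM: 3.3
    hill: 1.0
  INa:
    ic50_uM: 20.0
    hill: 1.0
  ICaL:
    ic50_uM: 15.0
    hill: 1.0
  IKs:
    ic50_uM: 30.0
    hill: 1.0
NT:
  IKr:
    ic50_uM: 4.0
    hill: 1.0
  INa:
    ic50_uM: 25.0
    hill: 1.0
  ICaL:
    ic50_uM: 20.0
    hill: 1.0
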