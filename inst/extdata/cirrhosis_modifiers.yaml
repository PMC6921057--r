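# Child-Pugh stratified pathophysiology for the cirrhosis population.
# Editable defaults: literature-informed stand-in values (Child-Pugh albumin
# bands; semi-mechanistic cirrhosis-population modelling literature).  They
# are NOT recoveries of any proprietary population library.
# Scalars multiply the healthy reference; albumin is an absolute target.
A:
  albumin_g_per_L: 36
  liver_volume_scalar: 0.90
  cyp_abundance_scalar: 0.60
  hepatic_flow_scalar: 0.90
  renal_flow_scalar: 0.90
B:
  albumin_g_per_L: 31
  liver_volume_scalar: 0.80
  cyp_abundance_scalar: 0.40
  hepatic_flow_scalar: 0.75
  renal_flow_scalar: 0.75
C:
  albumin_g_per_L: 26
  liver_volume_scalar: 0.65
  cyp_abundance_scalar: 0.25
  hepatic_flow_scalar: 0.60
  renal_flow_scalar: 0.60
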