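# Sirius-Red histology phantom profiles: interstitial collagen as a
# fraction of non-vessel myocardial area. The hyperoxia/air ratio is 2.2,
# matching the reported fold increase in cardiac fibrosis; absolute levels
# are plausible interstitial collagen fractions for neonatal mouse
# myocardium. cv is the between-specimen coefficient of variation used when
# sampling per-animal fractions.
vessel_fraction: 0.03
cv: 0.10
profiles:
  air_vehicle:
    collagen_fraction: 0.040
  hyperoxia_vehicle:
    collagen_fraction: 0.088
  hyperoxia_il1ra:
    collagen_fraction: 0.055
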