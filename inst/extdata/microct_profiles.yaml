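# Vessel-diameter condition profiles for the micro-CT phantom generator.
# Bin edges in micrometers; expected_counts are expected vessels per bin in
# one right-superior-lobe volume (absolute scale is a free parameter, only
# the relative structure is calibrated). Depletion factors are per-bin
# multiplicative factors relative to the air_vehicle reference: the
# small-vessel factors encode the published hyperoxia losses (-84% at
# 4-5 um, -83% at 5-6 um, -76% at 6-7 um); medium-vessel factors and the
# IL-1Ra rescue factors are plausible choices in the reported direction,
# since no numbers are printed for them.
bin_edges: [4, 5, 6, 7, 10, 15, 20, 30]
reference: air_vehicle
conditions:
  air_vehicle:
    expected_counts: [60, 50, 40, 30, 15, 8, 4]
  hyperoxia_vehicle:
    depletion: [0.16, 0.17, 0.24, 0.50, 0.60, 0.70, 0.80]
  hyperoxia_il1ra:
    depletion: [0.80, 0.85, 0.80, 0.90, 0.90, 0.95, 0.95]
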