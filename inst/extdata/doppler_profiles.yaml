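# Pulmonary-artery Doppler timing profiles (ms) for the echo phantom.
# tpv/rvet ratios match the reported group means: 0.32 air vehicle,
# 0.27 hyperoxia vehicle, 0.31 hyperoxia IL-1Ra. Peak velocity is in
# arbitrary units; heart period corresponds to ~400 bpm under isoflurane.
profiles:
  air_vehicle:
    tpv: 32
    rvet: 100
    peak_velocity: 700
    sample_rate: 1000
    heart_period: 150
  hyperoxia_vehicle:
    tpv: 27
    rvet: 100
    peak_velocity: 700
    sample_rate: 1000
    heart_period: 150
  hyperoxia_il1ra:
    tpv: 31
    rvet: 100
    peak_velocity: 700
    sample_rate: 1000
    heart_period: 150
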