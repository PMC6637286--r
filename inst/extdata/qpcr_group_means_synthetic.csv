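gene,group,mean_ct
Actb,air_vehicle,18.0000000
Actb,hyperoxia_vehicle,18.0000000
Actb,hyperoxia_il1ra,18.0000000
Lgals3,air_vehicle,28.0000000
Lgals3,hyperoxia_vehicle,26.4639471
Lgals3,hyperoxia_il1ra,27.0365259
Ccl2,air_vehicle,27.0000000
Ccl2,hyperoxia_vehicle,26.1520031
Ccl2,hyperoxia_il1ra,27.4383073
Nppb,air_vehicle,25.0000000
Nppb,hyperoxia_vehicle,25.0000000
Nppb,hyperoxia_il1ra,25.7131189
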