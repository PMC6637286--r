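# Four-parameter-logistic agonist profiles for the PCLS phantom, on the
# percent-initial-artery-area scale (bottom = area at zero drug, top = area
# at saturating drug). Maxima match the reported contractions (ET-1 43%,
# U46619 38% reduction); log EC50 values are set one log unit apart,
# matching the ~10-fold potency difference, and placed inside the tested
# concentration ranges.
profiles:
  et1:
    bottom: 100
    top: 57
    logec50: -8.5
    hill: 1.0
    concentrations: [1.0e-9, 2.512e-9, 6.31e-9, 1.585e-8, 3.981e-8, 1.0e-7]
  u46619:
    bottom: 100
    top: 62
    logec50: -7.5
    hill: 1.0
    concentrations: [3.0e-9, 9.655e-9, 3.107e-8, 1.0e-7, 3.218e-7, 1.0e-6]
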