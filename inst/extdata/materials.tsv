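# material constants table, v1
# density g/cm3; radiation_length g/cm2; mean_excitation_energy eV;
# electrons_per_gram 1/g
name	density	radiation_length	mean_excitation_energy	electrons_per_gram
water	1.0	36.08	75	3.343e23
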