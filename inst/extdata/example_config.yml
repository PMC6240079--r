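# Example crossflux configuration: any subset of keys may be given;
# the rest keep the package defaults.
band_width_m: 10
alpha: 0.05
gsl_days:
  temperate: 181
carbon_fractions:
  terrestrial_plant: 0.48
seed: 1
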