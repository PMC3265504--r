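# Standard full-serum binder set: genotype-averaged DBP plus albumin.
# Association constants are tagged /M and inverted to dissociation
# constants (uM) on load.
binder.DBP.concentration = 5 uM
binder.DBP.ka_25ohd = 7e8 /M
binder.DBP.ka_125d = 4e7 /M
binder.Albumin.concentration = 650 uM
binder.Albumin.ka_25ohd = 6e5 /M
binder.Albumin.ka_125d = 5.4e4 /M
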