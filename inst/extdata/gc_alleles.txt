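# Per-allele DBP (GC) parameters: literature-derived convenience defaults,
# user-overridable. Absolute per-allele affinities and plasma levels vary
# between reports; only the ratio concentration/Kd is identifiable from
# free/total measurements, so quantitative work should prefer the
# calibration route (calibrate_genotype_products) over these values.
# ka_*: association constants (/M); plasma_level: per-allele contribution
# to total plasma DBP.
allele.GC1F.ka_25ohd = 1.12e9 /M
allele.GC1F.ka_125d = 6.4e7 /M
allele.GC1F.plasma_level = 2.8 uM
allele.GC1S.ka_25ohd = 6.0e8 /M
allele.GC1S.ka_125d = 3.4e7 /M
allele.GC1S.plasma_level = 2.6 uM
allele.GC2.ka_25ohd = 3.6e8 /M
allele.GC2.ka_125d = 2.1e7 /M
allele.GC2.plasma_level = 2.3 uM
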