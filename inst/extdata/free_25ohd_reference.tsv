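genotype	total_25ohd_nM	free_25ohd_nM
GC1F/1F	25	0.006
GC1F/1S	25	0.008
GC1F/2	25	0.010
GC1S/1S	25	0.011
GC1S/2	25	0.014
GC2/2	25	0.018
GC1F/1F	50	0.013
GC1F/1S	50	0.016
GC1F/2	50	0.019
GC1S/1S	50	0.021
GC1S/2	50	0.028
GC2/2	50	0.037
GC1F/1F	100	0.025
GC1F/1S	100	0.032
GC1F/2	100	0.039
GC1S/1S	100	0.043
GC1S/2	100	0.055
GC2/2	100	0.074
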