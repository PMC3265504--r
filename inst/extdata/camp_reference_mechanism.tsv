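mechanism	genotype	total_25ohd_nM	total_125d_nM	activated	camp
both	GC1F/1F	50	0.1	FALSE	0.010
both	GC1F/1S	50	0.1	FALSE	0.010
both	GC1F/2	50	0.1	FALSE	0.010
both	GC1S/1S	50	0.1	FALSE	0.010
both	GC1S/2	50	0.1	FALSE	0.010
both	GC2/2	50	0.1	FALSE	0.010
both	GC1F/1F	50	0.1	TRUE	0.011
both	GC1F/1S	50	0.1	TRUE	0.012
both	GC1F/2	50	0.1	TRUE	0.015
both	GC1S/1S	50	0.1	TRUE	0.019
both	GC1S/2	50	0.1	TRUE	0.032
both	GC2/2	50	0.1	TRUE	0.072
intracrine	GC1F/1F	50	0	FALSE	0.010
intracrine	GC1F/1S	50	0	FALSE	0.010
intracrine	GC1F/2	50	0	FALSE	0.010
intracrine	GC1S/1S	50	0	FALSE	0.010
intracrine	GC1S/2	50	0	FALSE	0.010
intracrine	GC2/2	50	0	FALSE	0.010
intracrine	GC1F/1F	50	0	TRUE	0.010
intracrine	GC1F/1S	50	0	TRUE	0.011
intracrine	GC1F/2	50	0	TRUE	0.012
intracrine	GC1S/1S	50	0	TRUE	0.013
intracrine	GC1S/2	50	0	TRUE	0.019
intracrine	GC2/2	50	0	TRUE	0.036
endocrine	GC1F/1F	0	0.1	FALSE	0.010
endocrine	GC1F/1S	0	0.1	FALSE	0.010
endocrine	GC1F/2	0	0.1	FALSE	0.010
endocrine	GC1S/1S	0	0.1	FALSE	0.010
endocrine	GC1S/2	0	0.1	FALSE	0.010
endocrine	GC2/2	0	0.1	FALSE	0.010
endocrine	GC1F/1F	0	0.1	TRUE	0.010
endocrine	GC1F/1S	0	0.1	TRUE	0.010
endocrine	GC1F/2	0	0.1	TRUE	0.010
endocrine	GC1S/1S	0	0.1	TRUE	0.010
endocrine	GC1S/2	0	0.1	TRUE	0.010
endocrine	GC2/2	0	0.1	TRUE	0.010
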