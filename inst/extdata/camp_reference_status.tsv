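genotype	total_25ohd_nM	total_125d_nM	activated	camp
GC1F/1F	25	0.1	FALSE	0.010
GC1F/1S	25	0.1	FALSE	0.010
GC1F/2	25	0.1	FALSE	0.010
GC1S/1S	25	0.1	FALSE	0.010
GC1S/2	25	0.1	FALSE	0.010
GC2/2	25	0.1	FALSE	0.010
GC1F/1F	25	0.1	TRUE	0.010
GC1F/1S	25	0.1	TRUE	0.010
GC1F/2	25	0.1	TRUE	0.011
GC1S/1S	25	0.1	TRUE	0.011
GC1S/2	25	0.1	TRUE	0.013
GC2/2	25	0.1	TRUE	0.018
GC1F/1F	50	0.1	FALSE	0.010
GC1F/1S	50	0.1	FALSE	0.010
GC1F/2	50	0.1	FALSE	0.010
GC1S/1S	50	0.1	FALSE	0.010
GC1S/2	50	0.1	FALSE	0.010
GC2/2	50	0.1	FALSE	0.010
GC1F/1F	50	0.1	TRUE	0.011
GC1F/1S	50	0.1	TRUE	0.012
GC1F/2	50	0.1	TRUE	0.015
GC1S/1S	50	0.1	TRUE	0.019
GC1S/2	50	0.1	TRUE	0.032
GC2/2	50	0.1	TRUE	0.072
GC1F/1F	100	0.1	FALSE	0.010
GC1F/1S	100	0.1	FALSE	0.010
GC1F/2	100	0.1	FALSE	0.010
GC1S/1S	100	0.1	FALSE	0.010
GC1S/2	100	0.1	FALSE	0.010
GC2/2	100	0.1	FALSE	0.010
GC1F/1F	100	0.1	TRUE	0.019
GC1F/1S	100	0.1	TRUE	0.035
GC1F/2	100	0.1	TRUE	0.062
GC1S/1S	100	0.1	TRUE	0.090
GC1S/2	100	0.1	TRUE	0.199
GC2/2	100	0.1	TRUE	0.420
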