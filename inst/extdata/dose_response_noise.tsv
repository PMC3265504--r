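ligand	dose_nM	sd
125D	0.1	0.02
125D	0.2	0.03
125D	0.5	0.05
125D	1	0.05
125D	2	0.06
125D	4	0.06
125D	6	0.08
25OHD	1	0.02
25OHD	3	0.02
25OHD	10	0.03
25OHD	30	0.04
25OHD	100	0.05
25OHD	200	0.06
25OHD	300	0.08
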