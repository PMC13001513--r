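sample_id	group	replicate	generation	timepoint
A2C_r1_G0	A2C	1	0	G0
A2C_r1_G65	A2C	1	65	G65
C2A_r1_G0	C2A	1	0	G0
C2A_r1_G182	C2A	1	182	G182
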