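site	residue_index	epimer	pl_ratio	tilt_deg	splitting_khz	powder_flag	error_khz	segment
G2	2	D	1:400	0	7	FALSE	0.5	all
G2	2	D	1:400	90	-3.5	FALSE	0.5	all
L4	4	D	1:400	0	7	FALSE	0.5	all
L4	4	D	1:400	90	-3.5	FALSE	0.5	all
L5	5	D	1:400	0	7	FALSE	0.5	all
L5	5	D	1:400	90	-3.5	FALSE	0.5	all
I8	8	D	1:400	0	7	FALSE	0.5	all
I8	8	D	1:400	90	-3.5	FALSE	0.5	all
L10	10	D	1:400	0	7	FALSE	0.5	all
L10	10	D	1:400	90	-3.5	FALSE	0.5	all
L13	13	D	1:400	0	7	FALSE	0.5	all
L13	13	D	1:400	90	-3.5	FALSE	0.5	all
L16	16	D	1:400	0	7	FALSE	0.5	all
L16	16	D	1:400	90	-3.5	FALSE	0.5	all
I20	20	D	1:400	0	7	FALSE	0.5	all
I20	20	D	1:400	90	-3.5	FALSE	0.5	all
L21	21	D	1:400	0	7	FALSE	0.5	all
L21	21	D	1:400	90	-3.5	FALSE	0.5	all
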