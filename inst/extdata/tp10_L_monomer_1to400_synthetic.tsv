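site	residue_index	epimer	pl_ratio	tilt_deg	splitting_khz	powder_flag	error_khz	segment
G2	2	L	1:400	0	7	FALSE	0.5	N_terminal
G2	2	L	1:400	90	-3.5	FALSE	0.5	N_terminal
L4	4	L	1:400	0	7	FALSE	0.5	N_terminal
L4	4	L	1:400	90	-3.5	FALSE	0.5	N_terminal
L5	5	L	1:400	0	7	FALSE	0.5	N_terminal
L5	5	L	1:400	90	-3.5	FALSE	0.5	N_terminal
I8	8	L	1:400	0	7	FALSE	0.5	N_terminal
I8	8	L	1:400	90	-3.5	FALSE	0.5	N_terminal
L10	10	L	1:400	0	0.3062	FALSE	0.5	C_terminal
L10	10	L	1:400	90	-0.1531	FALSE	0.5	C_terminal
L13	13	L	1:400	0	14.4459	FALSE	0.5	C_terminal
L13	13	L	1:400	90	-7.2229	FALSE	0.5	C_terminal
L16	16	L	1:400	0	4.3309	FALSE	0.5	C_terminal
L16	16	L	1:400	90	-2.1654	FALSE	0.5	C_terminal
I20	20	L	1:400	0	13.8747	FALSE	0.5	C_terminal
I20	20	L	1:400	90	-6.9374	FALSE	0.5	C_terminal
L21	21	L	1:400	0	-4.4738	FALSE	0.5	C_terminal
L21	21	L	1:400	90	2.2369	FALSE	0.5	C_terminal
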