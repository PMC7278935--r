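species	fatty_acid	construct	percent	letter
sparus_aurata	24:0	elovl4a	14.6	a
sparus_aurata	24:0	elovl4b	11.3	a
sparus_aurata	24:0	control	12.1	a
sparus_aurata	26:0	elovl4a	49.5	b
sparus_aurata	26:0	elovl4b	68.2	a
sparus_aurata	26:0	control	75.0	a
sparus_aurata	28:0	elovl4a	20.8	c
sparus_aurata	28:0	elovl4b	14.1	b
sparus_aurata	28:0	control	8.6	a
sparus_aurata	30:0	elovl4a	11.0	b
sparus_aurata	30:0	elovl4b	4.5	a
sparus_aurata	30:0	control	2.7	a
sparus_aurata	32:0	elovl4a	3.3	b
sparus_aurata	32:0	elovl4b	1.5	a
sparus_aurata	32:0	control	1.0	a
sparus_aurata	34:0	elovl4a	0.7	a
sparus_aurata	34:0	elovl4b	0.3	a
sparus_aurata	34:0	control	0.3	a
solea_senegalensis	24:0	elovl4a	9.2	b
solea_senegalensis	24:0	elovl4b	9.5	b
solea_senegalensis	24:0	control	6.1	a
solea_senegalensis	26:0	elovl4a	72.1	b
solea_senegalensis	26:0	elovl4b	81.2	b
solea_senegalensis	26:0	control	58.3	a
solea_senegalensis	28:0	elovl4a	11.9	b
solea_senegalensis	28:0	elovl4b	5.7	c
solea_senegalensis	28:0	control	21.7	a
solea_senegalensis	30:0	elovl4a	5.5	b
solea_senegalensis	30:0	elovl4b	2.9	b
solea_senegalensis	30:0	control	11.5	a
solea_senegalensis	32:0	elovl4a	1.4	ab
solea_senegalensis	32:0	elovl4b	0.7	b
solea_senegalensis	32:0	control	2.4	a
solea_senegalensis	34:0	elovl4a	0.0	a
solea_senegalensis	34:0	elovl4b	0.0	a
solea_senegalensis	34:0	control	0.0	a
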