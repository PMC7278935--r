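species	construct	substrate	product	conversion
solea_senegalensis	elovl4a	18:4n-3	20:4n-3	4.5
solea_senegalensis	elovl4b	18:4n-3	20:4n-3	8.1
solea_senegalensis	elovl4a	18:4n-3	22:4n-3	19.6
solea_senegalensis	elovl4b	18:4n-3	22:4n-3	41.2
solea_senegalensis	elovl4a	18:4n-3	24:4n-3	39.5
solea_senegalensis	elovl4b	18:4n-3	24:4n-3	79.0
solea_senegalensis	elovl4a	18:4n-3	26:4n-3	39.6
solea_senegalensis	elovl4b	18:4n-3	26:4n-3	95.3
solea_senegalensis	elovl4a	18:4n-3	28:4n-3	100
solea_senegalensis	elovl4b	18:4n-3	28:4n-3	96.8
solea_senegalensis	elovl4a	18:4n-3	30:4n-3	100
solea_senegalensis	elovl4b	18:4n-3	30:4n-3	98.7
solea_senegalensis	elovl4a	18:4n-3	32:4n-3	65.4
solea_senegalensis	elovl4b	18:4n-3	32:4n-3	65.7
solea_senegalensis	elovl4a	18:4n-3	34:4n-3	n.d.
solea_senegalensis	elovl4b	18:4n-3	34:4n-3	1.7
solea_senegalensis	elovl4a	18:4n-3	36:4n-3	n.d.
solea_senegalensis	elovl4b	18:4n-3	36:4n-3	n.d.
solea_senegalensis	elovl4a	18:3n-6	20:3n-6	4.6
solea_senegalensis	elovl4b	18:3n-6	20:3n-6	6.2
solea_senegalensis	elovl4a	18:3n-6	22:3n-6	38.6
solea_senegalensis	elovl4b	18:3n-6	22:3n-6	40.8
solea_senegalensis	elovl4a	18:3n-6	24:3n-6	66.2
solea_senegalensis	elovl4b	18:3n-6	24:3n-6	66.0
solea_senegalensis	elovl4a	18:3n-6	26:3n-6	65.3
solea_senegalensis	elovl4b	18:3n-6	26:3n-6	89.1
solea_senegalensis	elovl4a	18:3n-6	28:3n-6	100
solea_senegalensis	elovl4b	18:3n-6	28:3n-6	91.9
solea_senegalensis	elovl4a	18:3n-6	30:3n-6	55.0
solea_senegalensis	elovl4b	18:3n-6	30:3n-6	90.4
solea_senegalensis	elovl4a	18:3n-6	32:3n-6	62.7
solea_senegalensis	elovl4b	18:3n-6	32:3n-6	17.8
solea_senegalensis	elovl4a	18:3n-6	34:3n-6	n.d.
solea_senegalensis	elovl4b	18:3n-6	34:3n-6	n.d.
solea_senegalensis	elovl4a	18:3n-6	36:3n-6	n.d.
solea_senegalensis	elovl4b	18:3n-6	36:3n-6	n.d.
solea_senegalensis	elovl4a	20:5n-3	22:5n-3	12.1
solea_senegalensis	elovl4b	20:5n-3	22:5n-3	30.9
solea_senegalensis	elovl4a	20:5n-3	24:5n-3	31.8
solea_senegalensis	elovl4b	20:5n-3	24:5n-3	75.1
solea_senegalensis	elovl4a	20:5n-3	26:5n-3	35.7
solea_senegalensis	elovl4b	20:5n-3	26:5n-3	87.4
solea_senegalensis	elovl4a	20:5n-3	28:5n-3	100
solea_senegalensis	elovl4b	20:5n-3	28:5n-3	96.9
solea_senegalensis	elovl4a	20:5n-3	30:5n-3	50.0
solea_senegalensis	elovl4b	20:5n-3	30:5n-3	98.9
solea_senegalensis	elovl4a	20:5n-3	32:5n-3	33.7
solea_senegalensis	elovl4b	20:5n-3	32:5n-3	82.9
solea_senegalensis	elovl4a	20:5n-3	34:5n-3	38.2
solea_senegalensis	elovl4b	20:5n-3	34:5n-3	14.5
solea_senegalensis	elovl4a	20:5n-3	36:5n-3	n.d.
solea_senegalensis	elovl4b	20:5n-3	36:5n-3	n.d.
solea_senegalensis	elovl4a	20:4n-6	22:4n-6	18.1
solea_senegalensis	elovl4b	20:4n-6	22:4n-6	33.1
solea_senegalensis	elovl4a	20:4n-6	24:4n-6	49.9
solea_senegalensis	elovl4b	20:4n-6	24:4n-6	73.4
solea_senegalensis	elovl4a	20:4n-6	26:4n-6	56.7
solea_senegalensis	elovl4b	20:4n-6	26:4n-6	85.1
solea_senegalensis	elovl4a	20:4n-6	28:4n-6	65.2
solea_senegalensis	elovl4b	20:4n-6	28:4n-6	94.3
solea_senegalensis	elovl4a	20:4n-6	30:4n-6	95.2
solea_senegalensis	elovl4b	20:4n-6	30:4n-6	95.9
solea_senegalensis	elovl4a	20:4n-6	32:4n-6	84.9
solea_senegalensis	elovl4b	20:4n-6	32:4n-6	51.8
solea_senegalensis	elovl4a	20:4n-6	34:4n-6	25.3
solea_senegalensis	elovl4b	20:4n-6	34:4n-6	2.7
solea_senegalensis	elovl4a	20:4n-6	36:4n-6	n.d.
solea_senegalensis	elovl4b	20:4n-6	36:4n-6	n.d.
solea_senegalensis	elovl4a	22:5n-3	24:5n-3	7.8
solea_senegalensis	elovl4b	22:5n-3	24:5n-3	44.3
solea_senegalensis	elovl4a	22:5n-3	26:5n-3	33.9
solea_senegalensis	elovl4b	22:5n-3	26:5n-3	87.9
solea_senegalensis	elovl4a	22:5n-3	28:5n-3	51.2
solea_senegalensis	elovl4b	22:5n-3	28:5n-3	97.0
solea_senegalensis	elovl4a	22:5n-3	30:5n-3	92.3
solea_senegalensis	elovl4b	22:5n-3	30:5n-3	99.0
solea_senegalensis	elovl4a	22:5n-3	32:5n-3	27.4
solea_senegalensis	elovl4b	22:5n-3	32:5n-3	82.5
solea_senegalensis	elovl4a	22:5n-3	34:5n-3	32.4
solea_senegalensis	elovl4b	22:5n-3	34:5n-3	16.2
solea_senegalensis	elovl4a	22:5n-3	36:5n-3	n.d.
solea_senegalensis	elovl4b	22:5n-3	36:5n-3	n.d.
solea_senegalensis	elovl4a	22:4n-6	24:4n-6	13.5
solea_senegalensis	elovl4b	22:4n-6	24:4n-6	37.2
solea_senegalensis	elovl4a	22:4n-6	26:4n-6	58.3
solea_senegalensis	elovl4b	22:4n-6	26:4n-6	85.5
solea_senegalensis	elovl4a	22:4n-6	28:4n-6	71.8
solea_senegalensis	elovl4b	22:4n-6	28:4n-6	94.5
solea_senegalensis	elovl4a	22:4n-6	30:4n-6	94.5
solea_senegalensis	elovl4b	22:4n-6	30:4n-6	96.3
solea_senegalensis	elovl4a	22:4n-6	32:4n-6	21.6
solea_senegalensis	elovl4b	22:4n-6	32:4n-6	53.9
solea_senegalensis	elovl4a	22:4n-6	34:4n-6	25.9
solea_senegalensis	elovl4b	22:4n-6	34:4n-6	5.0
solea_senegalensis	elovl4a	22:4n-6	36:4n-6	n.d.
solea_senegalensis	elovl4b	22:4n-6	36:4n-6	n.d.
solea_senegalensis	elovl4a	22:6n-3	24:6n-3	0.6
solea_senegalensis	elovl4b	22:6n-3	24:6n-3	5.1
solea_senegalensis	elovl4a	22:6n-3	26:6n-3	n.d.
solea_senegalensis	elovl4b	22:6n-3	26:6n-3	100
solea_senegalensis	elovl4a	22:6n-3	28:6n-3	n.d.
solea_senegalensis	elovl4b	22:6n-3	28:6n-3	100
solea_senegalensis	elovl4a	22:6n-3	30:6n-3	n.d.
solea_senegalensis	elovl4b	22:6n-3	30:6n-3	100
solea_senegalensis	elovl4a	22:6n-3	32:6n-3	n.d.
solea_senegalensis	elovl4b	22:6n-3	32:6n-3	22.3
solea_senegalensis	elovl4a	22:6n-3	34:6n-3	n.d.
solea_senegalensis	elovl4b	22:6n-3	34:6n-3	n.d.
solea_senegalensis	elovl4a	22:6n-3	36:6n-3	n.d.
solea_senegalensis	elovl4b	22:6n-3	36:6n-3	n.d.
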