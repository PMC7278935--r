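species	construct	substrate	product	conversion
sparus_aurata	elovl4a	18:4n-3	20:4n-3	2.5
sparus_aurata	elovl4b	18:4n-3	20:4n-3	2.7
sparus_aurata	elovl4a	18:4n-3	22:4n-3	9.7
sparus_aurata	elovl4b	18:4n-3	22:4n-3	12.5
sparus_aurata	elovl4a	18:4n-3	24:4n-3	5.6
sparus_aurata	elovl4b	18:4n-3	24:4n-3	49.9
sparus_aurata	elovl4a	18:4n-3	26:4n-3	n.d.
sparus_aurata	elovl4b	18:4n-3	26:4n-3	65.6
sparus_aurata	elovl4a	18:4n-3	28:4n-3	n.d.
sparus_aurata	elovl4b	18:4n-3	28:4n-3	n.d.
sparus_aurata	elovl4a	18:4n-3	30:4n-3	n.d.
sparus_aurata	elovl4b	18:4n-3	30:4n-3	n.d.
sparus_aurata	elovl4a	18:4n-3	32:4n-3	n.d.
sparus_aurata	elovl4b	18:4n-3	32:4n-3	n.d.
sparus_aurata	elovl4a	18:4n-3	34:4n-3	n.d.
sparus_aurata	elovl4b	18:4n-3	34:4n-3	n.d.
sparus_aurata	elovl4a	18:4n-3	36:4n-3	n.d.
sparus_aurata	elovl4b	18:4n-3	36:4n-3	n.d.
sparus_aurata	elovl4a	18:3n-6	20:3n-6	2.6
sparus_aurata	elovl4b	18:3n-6	20:3n-6	2.1
sparus_aurata	elovl4a	18:3n-6	22:3n-6	21.6
sparus_aurata	elovl4b	18:3n-6	22:3n-6	9.6
sparus_aurata	elovl4a	18:3n-6	24:3n-6	52.5
sparus_aurata	elovl4b	18:3n-6	24:3n-6	n.d.
sparus_aurata	elovl4a	18:3n-6	26:3n-6	57.1
sparus_aurata	elovl4b	18:3n-6	26:3n-6	n.d.
sparus_aurata	elovl4a	18:3n-6	28:3n-6	64.8
sparus_aurata	elovl4b	18:3n-6	28:3n-6	n.d.
sparus_aurata	elovl4a	18:3n-6	30:3n-6	90.0
sparus_aurata	elovl4b	18:3n-6	30:3n-6	n.d.
sparus_aurata	elovl4a	18:3n-6	32:3n-6	84.1
sparus_aurata	elovl4b	18:3n-6	32:3n-6	n.d.
sparus_aurata	elovl4a	18:3n-6	34:3n-6	41.3
sparus_aurata	elovl4b	18:3n-6	34:3n-6	n.d.
sparus_aurata	elovl4a	18:3n-6	36:3n-6	n.d.
sparus_aurata	elovl4b	18:3n-6	36:3n-6	n.d.
sparus_aurata	elovl4a	20:5n-3	22:5n-3	5.8
sparus_aurata	elovl4b	20:5n-3	22:5n-3	9.1
sparus_aurata	elovl4a	20:5n-3	24:5n-3	17.2
sparus_aurata	elovl4b	20:5n-3	24:5n-3	33.3
sparus_aurata	elovl4a	20:5n-3	26:5n-3	20.0
sparus_aurata	elovl4b	20:5n-3	26:5n-3	57.8
sparus_aurata	elovl4a	20:5n-3	28:5n-3	n.d.
sparus_aurata	elovl4b	20:5n-3	28:5n-3	86.8
sparus_aurata	elovl4a	20:5n-3	30:5n-3	n.d.
sparus_aurata	elovl4b	20:5n-3	30:5n-3	97.7
sparus_aurata	elovl4a	20:5n-3	32:5n-3	n.d.
sparus_aurata	elovl4b	20:5n-3	32:5n-3	72.7
sparus_aurata	elovl4a	20:5n-3	34:5n-3	n.d.
sparus_aurata	elovl4b	20:5n-3	34:5n-3	8.1
sparus_aurata	elovl4a	20:5n-3	36:5n-3	n.d.
sparus_aurata	elovl4b	20:5n-3	36:5n-3	n.d.
sparus_aurata	elovl4a	20:4n-6	22:4n-6	10.9
sparus_aurata	elovl4b	20:4n-6	22:4n-6	8.9
sparus_aurata	elovl4a	20:4n-6	24:4n-6	31.0
sparus_aurata	elovl4b	20:4n-6	24:4n-6	30.2
sparus_aurata	elovl4a	20:4n-6	26:4n-6	37.1
sparus_aurata	elovl4b	20:4n-6	26:4n-6	55.9
sparus_aurata	elovl4a	20:4n-6	28:4n-6	39.0
sparus_aurata	elovl4b	20:4n-6	28:4n-6	81.0
sparus_aurata	elovl4a	20:4n-6	30:4n-6	88.6
sparus_aurata	elovl4b	20:4n-6	30:4n-6	37.8
sparus_aurata	elovl4a	20:4n-6	32:4n-6	83.6
sparus_aurata	elovl4b	20:4n-6	32:4n-6	n.d.
sparus_aurata	elovl4a	20:4n-6	34:4n-6	73.7
sparus_aurata	elovl4b	20:4n-6	34:4n-6	n.d.
sparus_aurata	elovl4a	20:4n-6	36:4n-6	11.4
sparus_aurata	elovl4b	20:4n-6	36:4n-6	n.d.
sparus_aurata	elovl4a	22:5n-3	24:5n-3	3.4
sparus_aurata	elovl4b	22:5n-3	24:5n-3	12.6
sparus_aurata	elovl4a	22:5n-3	26:5n-3	19.8
sparus_aurata	elovl4b	22:5n-3	26:5n-3	52.2
sparus_aurata	elovl4a	22:5n-3	28:5n-3	26.0
sparus_aurata	elovl4b	22:5n-3	28:5n-3	86.3
sparus_aurata	elovl4a	22:5n-3	30:5n-3	85.6
sparus_aurata	elovl4b	22:5n-3	30:5n-3	96.5
sparus_aurata	elovl4a	22:5n-3	32:5n-3	74.2
sparus_aurata	elovl4b	22:5n-3	32:5n-3	64.4
sparus_aurata	elovl4a	22:5n-3	34:5n-3	63.0
sparus_aurata	elovl4b	22:5n-3	34:5n-3	5.3
sparus_aurata	elovl4a	22:5n-3	36:5n-3	n.d.
sparus_aurata	elovl4b	22:5n-3	36:5n-3	n.d.
sparus_aurata	elovl4a	22:4n-6	24:4n-6	8.2
sparus_aurata	elovl4b	22:4n-6	24:4n-6	10.4
sparus_aurata	elovl4a	22:4n-6	26:4n-6	35.1
sparus_aurata	elovl4b	22:4n-6	26:4n-6	43.1
sparus_aurata	elovl4a	22:4n-6	28:4n-6	45.5
sparus_aurata	elovl4b	22:4n-6	28:4n-6	71.8
sparus_aurata	elovl4a	22:4n-6	30:4n-6	90.8
sparus_aurata	elovl4b	22:4n-6	30:4n-6	83.0
sparus_aurata	elovl4a	22:4n-6	32:4n-6	78.7
sparus_aurata	elovl4b	22:4n-6	32:4n-6	19.5
sparus_aurata	elovl4a	22:4n-6	34:4n-6	54.6
sparus_aurata	elovl4b	22:4n-6	34:4n-6	n.d.
sparus_aurata	elovl4a	22:4n-6	36:4n-6	7.2
sparus_aurata	elovl4b	22:4n-6	36:4n-6	n.d.
sparus_aurata	elovl4a	22:6n-3	24:6n-3	0.4
sparus_aurata	elovl4b	22:6n-3	24:6n-3	1.8
sparus_aurata	elovl4a	22:6n-3	26:6n-3	n.d.
sparus_aurata	elovl4b	22:6n-3	26:6n-3	100
sparus_aurata	elovl4a	22:6n-3	28:6n-3	n.d.
sparus_aurata	elovl4b	22:6n-3	28:6n-3	100
sparus_aurata	elovl4a	22:6n-3	30:6n-3	n.d.
sparus_aurata	elovl4b	22:6n-3	30:6n-3	40.2
sparus_aurata	elovl4a	22:6n-3	32:6n-3	n.d.
sparus_aurata	elovl4b	22:6n-3	32:6n-3	61.3
sparus_aurata	elovl4a	22:6n-3	34:6n-3	n.d.
sparus_aurata	elovl4b	22:6n-3	34:6n-3	n.d.
sparus_aurata	elovl4a	22:6n-3	36:6n-3	n.d.
sparus_aurata	elovl4b	22:6n-3	36:6n-3	n.d.
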