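material	density	element	mass_fraction
water	1	H	0.111898
water	1	O	0.888102
soft_tissue	1.04	H	0.102
soft_tissue	1.04	C	0.143
soft_tissue	1.04	N	0.034
soft_tissue	1.04	O	0.708
soft_tissue	1.04	Na	0.002
soft_tissue	1.04	P	0.003
soft_tissue	1.04	S	0.003
soft_tissue	1.04	Cl	0.002
soft_tissue	1.04	K	0.003
bone	1.92	H	0.034
bone	1.92	C	0.155
bone	1.92	N	0.042
bone	1.92	O	0.435
bone	1.92	Na	0.001
bone	1.92	Mg	0.002
bone	1.92	P	0.103
bone	1.92	S	0.003
bone	1.92	Ca	0.225
lung	0.296	H	0.103
lung	0.296	C	0.105
lung	0.296	N	0.031
lung	0.296	O	0.749
lung	0.296	Na	0.002
lung	0.296	P	0.002
lung	0.296	S	0.003
lung	0.296	Cl	0.003
lung	0.296	K	0.002
air	0.001205	N	0.755
air	0.001205	O	0.232
air	0.001205	Ar	0.013
tungsten	19.3	W	1
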