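profile	gene	exon	cterm	proportion
pre_gastrulation	jnk1a	Ex7	Sh	0.12
pre_gastrulation	jnk1a	Ex7	Lg	0.28
pre_gastrulation	jnk1a	Ex8	Sh	0.12
pre_gastrulation	jnk1a	Ex8	Lg	0.28
pre_gastrulation	jnk1b	Ex7	Sh	0.02
pre_gastrulation	jnk1b	Ex7	Lg	0.01
pre_gastrulation	jnk1b	Ex8	Sh	0.14
pre_gastrulation	jnk1b	Ex8	Lg	0.03
larval_120hpf	jnk1a	Ex7	Sh	0.04
larval_120hpf	jnk1a	Ex7	Lg	0.07
larval_120hpf	jnk1a	Ex8	Sh	0.04
larval_120hpf	jnk1a	Ex8	Lg	0.05
larval_120hpf	jnk1b	Ex7	Sh	0.40
larval_120hpf	jnk1b	Ex7	Lg	0.05
larval_120hpf	jnk1b	Ex8	Sh	0.30
larval_120hpf	jnk1b	Ex8	Lg	0.05
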