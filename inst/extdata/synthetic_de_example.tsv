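gene	log2fc	p
NOS1	0.71	0.04
NOS3	-0.8	0.004
AKR1B10	0.89	0.03
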