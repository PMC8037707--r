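metabolite	gene	pathway
L-Arginine	NOS1	hsa00330
L-Arginine	NOS3	hsa00330
L-Arginine	AKR1B10	hsa00790
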