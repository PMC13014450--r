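protein	name	chain	start	end	class
TmY	alpha3	A	62	72	alpha
TmY	alpha4	A	87	95	alpha
TmY	gamma_turn_loop	A	55	61	coil
EcY	alpha3	A	65	74	alpha
EcY	alpha4	A	92	100	alpha
EcY	alpha5	A	113	127	alpha
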