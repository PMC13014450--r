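basic	acidic	elements	f_302	f_328	f_374	f_400	f_450
Arg22	Glu35	alpha1-beta2	0.980	0.956	0.859	0.768	0.272
Lys45	Asp41	alpha2	0.964	0.951	0.912	0.898	0.695
Lys109	Asp57	beta3-beta5/alpha5	0.812	0.727	0.515	0.434	0.173
Lys109	Asp12	beta1/alpha1-beta5/alpha5	0.636	0.527	0.215	0.092	0.023
Arg18	Glu35	alpha1-beta2	0.634	0.718	0.783	0.804	0.197
Arg18	Glu37	alpha1-beta2/alpha2	0.398	0.346	0.418	0.451	0.167
Lys91	Glu89	beta4/alpha4	0.375	0.334	0.219	0.179	0.165
Lys70	Glu67	alpha3	0.300	0.348	0.412	0.267	0.372
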