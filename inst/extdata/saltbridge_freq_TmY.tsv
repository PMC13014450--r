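basic	acidic	elements	f_302	f_328	f_374	f_400	f_450
Lys104	Asp9	beta1/alpha1-beta5/alpha5	0.981	0.987	0.979	0.970	0.486
Lys104	Asp54	beta3-beta5/alpha5	0.948	0.978	0.950	0.944	0.885
Lys24	Asp20	alpha1	0.909	0.881	0.856	0.849	0.740
Arg15	Glu32	alpha1-beta2	0.682	0.701	0.715	0.712	0.676
Lys19	Glu32	alpha1-beta2	0.668	0.649	0.618	0.636	0.622
Arg110	Glu113	alpha5	0.662	0.487	0.505	0.488	0.466
Lys77	Asp49	alpha2/beta3-alpha3/beta4	0.560	0.533	0.453	0.482	0.475
Lys117	Asp100	beta5-alpha5	0.554	0.593	0.625	0.630	0.524
Arg110	Asp100	beta5-alpha5	0.491	0.605	0.714	0.741	0.570
Arg37	Glu68	alpha2-alpha3	0.468	0.501	0.372	0.383	0.173
Lys95	Glu92	alpha4	0.427	0.462	0.523	0.552	0.346
Arg4	Glu28	beta1-beta2	0.420	0.424	0.422	0.426	0.435
Arg37	Asp64	alpha2-alpha3	0.404	0.517	0.334	0.384	0.318
Lys71	Glu68	alpha3	0.382	0.465	0.469	0.470	0.516
Lys44	Glu41	alpha2	0.362	0.371	0.424	0.432	0.463
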