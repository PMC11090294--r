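marker	genotype	mean	sd	count	lsd_letter
gga1_168m	RR	0.1194	0.9893	1691	a
gga1_168m	RA	-0.1183	0.9861	1075	b
gga1_168m	AA	-0.4452	0.8843	164	c
gga1_171m	RR	0.1979	1.0384	692	a
gga1_171m	RA	0.0010	1.0069	1552	b
gga1_171m	AA	-0.2019	0.8765	686	c
gga1_171v	RR	-0.1751	0.9158	989	a
gga1_171v	RA	0.0375	1.0125	1538	b
gga1_171v	AA	0.2865	1.0331	403	c
gga1_172v	RR	-0.1306	0.8909	705	a
gga1_172v	RA	0.0004	1.0117	1574	b
gga1_172v	AA	0.1405	1.0418	651	c
gga1_174v	RR	0.0770	1.0208	939	a
gga1_174v	RA	-0.0050	1.0139	1509	b
gga1_174v	AA	-0.1343	0.8617	482	c
gga1_178v	RR	0.0638	1.0719	1071	a
gga1_178v	RA	-0.0053	0.9631	1426	a
gga1_178v	AA	-0.1404	0.8803	433	b
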