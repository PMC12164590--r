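subunit	state	ratio	flag
PsbA	SC	0.01	
PsbA	Dimers	0.09	
PsbA	Monomers/RC47	0.32	
PsbA	RCII	32.2	
PsbA	CP43_mod	NA	ND
PsbA	D1_mod/PsbE/F	2.2	
PsbB	SC	0.01	
PsbB	Dimers	0.07	
PsbB	Monomers/RC47	0.28	
PsbB	RCII	NA	ND
PsbB	CP43_mod	NA	ND
PsbB	D1_mod/PsbE/F	NA	nd/ND
PsbC	SC	0.02	
PsbC	Dimers	0.09	
PsbC	Monomers/RC47	0.24	
PsbC	RCII	NA	ND
PsbC	CP43_mod	10.5	
PsbC	D1_mod/PsbE/F	NA	ND
PsbD	SC	0.03	
PsbD	Dimers	0.12	
PsbD	Monomers/RC47	0.4	
PsbD	RCII	77.1	
PsbD	CP43_mod	NA	ND
PsbD	D1_mod/PsbE/F	NA	ND
PsbE	SC	0.02	
PsbE	Dimers	0.05	
PsbE	Monomers/RC47	0.26	
PsbE	RCII	NA	ND
PsbE	CP43_mod	NA	ND
PsbE	D1_mod/PsbE/F	15.5	
PsbF	SC	NA	nd
PsbF	Dimers	NA	nd
PsbF	Monomers/RC47	0.5	
PsbF	RCII	NA	nd/ND
PsbF	CP43_mod	NA	nd/ND
PsbF	D1_mod/PsbE/F	NA	ND
PsbH	SC	NA	nd
PsbH	Dimers	NA	nd
PsbH	Monomers/RC47	0.11	
PsbH	RCII	NA	nd/ND
PsbH	CP43_mod	NA	nd/ND
PsbH	D1_mod/PsbE/F	NA	nd/ND
PsbJ	SC	0.01	
PsbJ	Dimers	0.15	
PsbJ	Monomers/RC47	0.14	
PsbJ	RCII	NA	nd/ND
PsbJ	CP43_mod	NA	nd/ND
PsbJ	D1_mod/PsbE/F	NA	nd/ND
PsbL	SC	NA	nd
PsbL	Dimers	0.01	
PsbL	Monomers/RC47	0.09	
PsbL	RCII	NA	ND
PsbL	CP43_mod	NA	nd/ND
PsbL	D1_mod/PsbE/F	NA	nd/ND
PSBO	SC	0.01	
PSBO	Dimers	0.02	
PSBO	Monomers/RC47	NA	nd
PSBO	RCII	NA	nd
PSBO	CP43_mod	NA	nd
PSBO	D1_mod/PsbE/F	0.6	
PBA1	SC	NA	nd
PBA1	Dimers	NA	nd/ND
PBA1	Monomers/RC47	0.83	
PBA1	RCII	NA	nd/ND
PBA1	CP43_mod	NA	nd/ND
PBA1	D1_mod/PsbE/F	1.3	
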