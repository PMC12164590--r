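group	subunit	ratio	canonical
ATP synthase	AtpA	1.03	TRUE
ATP synthase	AtpB	1.07	TRUE
ATP synthase	ATPC	0.91	TRUE
ATP synthase	ATPD	1.08	TRUE
ATP synthase	AtpE	0.86	TRUE
ATP synthase	AtpF	1.06	TRUE
ATP synthase	ATPG	1.03	TRUE
ATP synthase	AtpI	0.82	TRUE
Cyt b6f	PetA	1.97	TRUE
Cyt b6f	PetB	1.86	TRUE
Cyt b6f	PETC	1.99	TRUE
Cyt b6f	PetD	1.69	TRUE
Cyt b6f	PETM	1.88	TRUE
Cyt b6f	PETO	0.81	TRUE
PSII core	PsbA	0.15	TRUE
PSII core	PsbB	0.08	TRUE
PSII core	PsbC	0.21	TRUE
PSII core	PsbD	0.21	TRUE
PSII core	PsbE	0.15	TRUE
PSII core	PsbF	0.10	TRUE
PSII core	PsbH	0.005	TRUE
PSII core	PsbJ	0.42	TRUE
PSII core	PsbL	0.19	TRUE
PSII core	PBA1	1.26	FALSE
OEC	PSBO	0.26	TRUE
OEC	PSBP1	0.45	TRUE
OEC	PSBP3	14.83	TRUE
OEC	PSBP4	1.46	TRUE
OEC	PSBP6	1.96	TRUE
OEC	PSBQ	0.35	TRUE
OEC	PSBR	0.27	TRUE
LHCII	LHCB4	0.61	TRUE
LHCII	LHCB5	1.24	TRUE
LHCII	LHCB7	5.13	TRUE
LHCII	LHCBM1	0.58	TRUE
LHCII	LHCBM3	0.47	TRUE
LHCII	LHCBM5	0.55	TRUE
LHCII	LHCBM6	0.46	TRUE
LHCII	LHCBM8	0.44	TRUE
LHCII	LHCBM9	0.43	TRUE
PSI core	PsaA	1.03	TRUE
PSI core	PsaB	0.80	TRUE
PSI core	PsaC	0.70	TRUE
PSI core	PSAD	0.95	TRUE
PSI core	PSAE	0.57	TRUE
PSI core	PSAF	0.96	TRUE
PSI core	PSAG	1.06	TRUE
PSI core	PSAH	0.88	TRUE
PSI core	PsaJ	0.30	TRUE
PSI core	PSAK	0.75	TRUE
PSI core	PSAL	0.90	TRUE
PSI core	PSAN	0.50	TRUE
LHCI	LHCA1	0.81	TRUE
LHCI	LHCA2	0.60	TRUE
LHCI	LHCA3	0.89	TRUE
LHCI	LHCA4	0.35	TRUE
LHCI	LHCA5	0.89	TRUE
LHCI	LHCA6	0.42	TRUE
LHCI	LHCA7	1.12	TRUE
LHCI	LHCA8	1.26	TRUE
LHCI	LHCA9	0.62	TRUE
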