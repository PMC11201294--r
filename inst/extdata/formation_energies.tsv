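species	phase	charge	n_C	n_H	n_O	dGf_kJ_mol	dHf_kJ_mol	source
acetate	aqueous	-1	2	3	2	-369.32	-486.0	Shock & Helgeson (1990) aqueous organic species compilation
propionate	aqueous	-1	3	5	2	-363.08	-510.7	Shock & Helgeson (1990) aqueous organic species compilation
H+	proton	1	0	1	0	0	0	conventional standard state (unit activity, zero formation energy)
H2	gas	0	0	2	0	0	0	Hanselmann (1991) microbial ecology energetics tables
H2O	liquid-water	0	0	2	1	-237.18	-285.83	Hanselmann (1991) microbial ecology energetics tables
CO2	gas	0	1	0	2	-394.36	-393.51	Hanselmann (1991) microbial ecology energetics tables
CH4	gas	0	1	4	0	-50.75	-74.81	Hanselmann (1991) microbial ecology energetics tables
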