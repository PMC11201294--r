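name	metal_class	pattern	group_hint	probe	source
FeFe_L1	FeFe	TSC[CS]P[A-Z]W	A	TSCCPAW	canonical H-cluster L1 signature (Vignais et al. 2001)
FeFe_L2	FeFe	MPC[A-Z]{2}K[A-Z]{2}E	A	MPCTAKSME	canonical H-cluster L2 signature (Vignais et al. 2001)
FeFe_L3	FeFe	E[A-Z]MAC[A-Z]{2}GC[A-Z]{2}G	A	ERMACPGGCVGG	canonical H-cluster L3 signature (Vignais et al. 2001)
NiFe_L1	NiFe	R[A-Z]C[GS][A-Z]C	NA	RICGVC	N-terminal CxxC nickel-binding motif (Vignais et al. 2001)
NiFe_L2	NiFe	DPC[A-Z]{2}C[A-Z]{2}[HR]	NA	DPCLACSTH	C-terminal DPCxxCxxH nickel-binding motif (Vignais et al. 2001)
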