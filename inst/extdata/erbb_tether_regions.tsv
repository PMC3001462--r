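refpos	region	tether
690	JM segment	NLT
694	JM segment	NLT
695	JM segment	NLT
700	JM segment	NLT
705	JM-kinase linker	NLT
706	JM-kinase linker	NLT
708	JM-kinase linker	NLT
709	JM-kinase linker	NLT
711	JM-kinase linker	NLT
714	JM-kinase linker	NLT
731	beta2-beta3 loop	NLT
733	beta2-beta3 loop	NLT
735	beta2-beta3 loop	NLT
736	beta2-beta3 loop	NLT
738	beta2-beta3 loop	NLT
739	beta2-beta3 loop	NLT
741	beta3 strand	NLT
764	C-helix	NLT
768	C-helix	NLT
784	beta4-beta5 loop	NLT
791	inter-lobe linker	NLT
794	inter-lobe linker	NLT
797	inter-lobe linker	NLT
802	D-helix	CLT
810	E-helix	CLT
816	E-helix	CLT
817	E-helix	CLT
848	beta8 strand	CLT
852	C-lobe hinge	NLT
861	activation loop	CLT
904	F-helix	CLT
938	G-H loop	CLT
941	H-helix	CLT
942	H-helix	CLT
968	I-helix	CLT
973	C-terminal tail	CLT
976	C-terminal tail	CLT
984	C-terminal tail	CLT
994	C-terminal tail	CLT
997	AP-2 helix	AST
1001	AP-2 helix	AST
1012	C-terminal tail	NLT
1014	C-terminal tail	NLT
1016	C-terminal tail	NLT
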