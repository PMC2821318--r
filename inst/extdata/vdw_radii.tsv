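residue_context	atom_name	radius_A
*	C	1.50
*	N	1.55
*	ND1	1.55
*	ND2	1.55
*	NE	1.55
*	NE1	1.55
*	NE2	1.55
*	NH1	1.55
*	NH2	1.55
*	NZ	1.55
*	O	1.40
*	OD1	1.40
*	OD2	1.40
*	OE1	1.40
*	OE2	1.40
*	OG	1.40
*	OG1	1.40
*	OH	1.40
*	SD	2.00
*	SG	2.00
*	CA	2.00
*	CB	2.00
*	CD	2.00
*	CD1	2.00
*	CD2	2.00
*	CE	2.00
*	CG	2.00
*	CG1	2.00
*	CG2	2.00
*	CH3	2.00
*	CZ	2.00
aromatic	CG	1.75
aromatic	CD1	1.75
aromatic	CD2	1.75
aromatic	CE1	1.75
aromatic	CE2	1.75
aromatic	CE3	1.75
aromatic	CZ	1.75
aromatic	CZ2	1.75
aromatic	CZ3	1.75
aromatic	CH2	1.75
wildcard	C**	2.00
wildcard	O**	1.44
wildcard	S**	2.00
wildcard	F**	2.00
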