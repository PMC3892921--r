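res_name	atom_name	class
*	N	donor
*	CA	neutral
*	C	neutral
*	O	acceptor
*	OXT	acceptor
ALA	CB	hydrophobic
ARG	CB	hydrophobic
ARG	CG	hydrophobic
ARG	CD	neutral
ARG	NE	donor
ARG	CZ	neutral
ARG	NH1	donor
ARG	NH2	donor
ASN	CB	hydrophobic
ASN	CG	neutral
ASN	OD1	acceptor
ASN	ND2	donor
ASP	CB	hydrophobic
ASP	CG	neutral
ASP	OD1	acceptor
ASP	OD2	acceptor
CYS	CB	neutral
CYS	SG	neutral
GLN	CB	hydrophobic
GLN	CG	hydrophobic
GLN	CD	neutral
GLN	OE1	acceptor
GLN	NE2	donor
GLU	CB	hydrophobic
GLU	CG	hydrophobic
GLU	CD	neutral
GLU	OE1	acceptor
GLU	OE2	acceptor
HIS	CB	hydrophobic
HIS	CG	aromatic
HIS	ND1	hydrophilic
HIS	CD2	aromatic
HIS	CE1	aromatic
HIS	NE2	hydrophilic
ILE	CB	hydrophobic
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
ILE	CD	hydrophobic
LEU	CB	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
LYS	CB	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
LYS	CE	neutral
LYS	NZ	donor
MET	CB	hydrophobic
MET	CG	neutral
MET	SD	neutral
MET	CE	neutral
PHE	CB	hydrophobic
PHE	CG	aromatic
PHE	CD1	aromatic
PHE	CD2	aromatic
PHE	CE1	aromatic
PHE	CE2	aromatic
PHE	CZ	aromatic
PRO	N	neutral
PRO	CB	hydrophobic
PRO	CG	hydrophobic
PRO	CD	neutral
SER	CB	neutral
SER	OG	hydrophilic
THR	CB	neutral
THR	OG1	hydrophilic
THR	CG2	hydrophobic
TRP	CB	hydrophobic
TRP	CG	aromatic
TRP	CD1	aromatic
TRP	CD2	aromatic
TRP	NE1	donor
TRP	CE2	aromatic
TRP	CE3	aromatic
TRP	CZ2	aromatic
TRP	CZ3	aromatic
TRP	CH2	aromatic
TYR	CB	hydrophobic
TYR	CG	aromatic
TYR	CD1	aromatic
TYR	CD2	aromatic
TYR	CE1	aromatic
TYR	CE2	aromatic
TYR	CZ	aromatic
TYR	OH	hydrophilic
VAL	CB	hydrophobic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
MSE	CB	hydrophobic
MSE	CG	neutral
MSE	SE	neutral
MSE	CE	neutral
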