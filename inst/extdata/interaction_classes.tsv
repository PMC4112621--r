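res_name	atom_name	class
THR	OG1	HBD
SER	OG	HBD
GLN	NE2	HBA
ASN	ND2	HBA
TYR	O	HBA
TYR	N	HBD
TYR	OH	HBD
TYR	CD1	CRing
TYR	CD2	CRing
TYR	CE1	CRing
TYR	CE2	CRing
TYR	CZ	CRing
TYR	CG	CRing
CYS	SG	Sulfur
MET	CE	vdW
MET	SD	Sulfur
ALA	CB	vdW
PRO	CB	vdW
PRO	CD	vdW
PRO	CG	vdW
LEU	CD1	vdW
LEU	CD2	vdW
LEU	CG	vdW
VAL	CG1	vdW
VAL	CG2	vdW
VAL	CB	vdW
ILE	CD1	vdW
ASP	OD1	HBA
ASP	OD2	IonNeg
GLU	OE1	HBA
GLU	OE2	IonNeg
LYS	NZ	IonPos
ARG	NH1	IonPos
ARG	NH2	IonPos
HIS	NE1	IonPos
HIS	NE2	IonPos
HIS	CD1	CRing
HIS	CE1	CRing
HIS	CD2	CRing
HIS	CE2	CRing
HIS	CG	CRing
PHE	CG	CRing
PHE	CD1	CRing
PHE	CE1	CRing
PHE	CZ	CRing
PHE	CE2	CRing
PHE	CD2	CRing
TRP	NE1	HBD
TRP	CD2	CRing
TRP	CE2	CRing
TRP	CZ2	CRing
TRP	CH2	CRing
TRP	CZ3	CRing
TRP	CE3	CRing
GLY	*	None
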