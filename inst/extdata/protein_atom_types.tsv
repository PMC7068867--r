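# Physicochemical typing of heavy atoms of the 20 standard amino acids.
# Columns: residue_name<TAB>atom_name<TAB>comma-separated types ('-' = untyped).
# Vocabulary: acceptor, aromatic, donor, hydrophobic, negative, positive.
# Conventions: backbone N donor (PRO excepted), backbone O acceptor, OXT
# acceptor+negative; carbons hydrophobic when all heavy neighbours are carbon;
# ring atoms of PHE/TYR/TRP/HIS aromatic; carboxylates acceptor+negative;
# LYS NZ and ARG NE/NH1/NH2 donor+positive; HIS ring N neutral donor+acceptor
# (pH 7 tautomer); SER/THR/TYR hydroxyls donor+acceptor.
ALA	N	donor
ALA	CA	-
ALA	C	-
ALA	O	acceptor
ALA	OXT	acceptor,negative
ALA	CB	hydrophobic
ARG	N	donor
ARG	CA	-
ARG	C	-
ARG	O	acceptor
ARG	OXT	acceptor,negative
ARG	CB	hydrophobic
ARG	CG	hydrophobic
ARG	CD	-
ARG	NE	donor,positive
ARG	CZ	-
ARG	NH1	donor,positive
ARG	NH2	donor,positive
ASN	N	donor
ASN	CA	-
ASN	C	-
ASN	O	acceptor
ASN	OXT	acceptor,negative
ASN	CB	hydrophobic
ASN	CG	-
ASN	OD1	acceptor
ASN	ND2	donor
ASP	N	donor
ASP	CA	-
ASP	C	-
ASP	O	acceptor
ASP	OXT	acceptor,negative
ASP	CB	hydrophobic
ASP	CG	-
ASP	OD1	acceptor,negative
ASP	OD2	acceptor,negative
CYS	N	donor
CYS	CA	-
CYS	C	-
CYS	O	acceptor
CYS	OXT	acceptor,negative
CYS	CB	-
CYS	SG	donor
GLN	N	donor
GLN	CA	-
GLN	C	-
GLN	O	acceptor
GLN	OXT	acceptor,negative
GLN	CB	hydrophobic
GLN	CG	hydrophobic
GLN	CD	-
GLN	OE1	acceptor
GLN	NE2	donor
GLU	N	donor
GLU	CA	-
GLU	C	-
GLU	O	acceptor
GLU	OXT	acceptor,negative
GLU	CB	hydrophobic
GLU	CG	hydrophobic
GLU	CD	-
GLU	OE1	acceptor,negative
GLU	OE2	acceptor,negative
GLY	N	donor
GLY	CA	-
GLY	C	-
GLY	O	acceptor
GLY	OXT	acceptor,negative
HIS	N	donor
HIS	CA	-
HIS	C	-
HIS	O	acceptor
HIS	OXT	acceptor,negative
HIS	CB	hydrophobic
HIS	CG	aromatic
HIS	ND1	acceptor,aromatic,donor
HIS	CD2	aromatic
HIS	CE1	aromatic
HIS	NE2	acceptor,aromatic,donor
ILE	N	donor
ILE	CA	-
ILE	C	-
ILE	O	acceptor
ILE	OXT	acceptor,negative
ILE	CB	hydrophobic
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
LEU	N	donor
LEU	CA	-
LEU	C	-
LEU	O	acceptor
LEU	OXT	acceptor,negative
LEU	CB	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
LYS	N	donor
LYS	CA	-
LYS	C	-
LYS	O	acceptor
LYS	OXT	acceptor,negative
LYS	CB	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
LYS	CE	-
LYS	NZ	donor,positive
MET	N	donor
MET	CA	-
MET	C	-
MET	O	acceptor
MET	OXT	acceptor,negative
MET	CB	hydrophobic
MET	CG	-
MET	SD	-
MET	CE	-
PHE	N	donor
PHE	CA	-
PHE	C	-
PHE	O	acceptor
PHE	OXT	acceptor,negative
PHE	CB	hydrophobic
PHE	CG	aromatic,hydrophobic
PHE	CD1	aromatic,hydrophobic
PHE	CD2	aromatic,hydrophobic
PHE	CE1	aromatic,hydrophobic
PHE	CE2	aromatic,hydrophobic
PHE	CZ	aromatic,hydrophobic
PRO	N	-
PRO	CA	-
PRO	C	-
PRO	O	acceptor
PRO	OXT	acceptor,negative
PRO	CB	hydrophobic
PRO	CG	hydrophobic
PRO	CD	-
SER	N	donor
SER	CA	-
SER	C	-
SER	O	acceptor
SER	OXT	acceptor,negative
SER	CB	-
SER	OG	acceptor,donor
THR	N	donor
THR	CA	-
THR	C	-
THR	O	acceptor
THR	OXT	acceptor,negative
THR	CB	-
THR	OG1	acceptor,donor
THR	CG2	hydrophobic
TRP	N	donor
TRP	CA	-
TRP	C	-
TRP	O	acceptor
TRP	OXT	acceptor,negative
TRP	CB	hydrophobic
TRP	CG	aromatic,hydrophobic
TRP	CD1	aromatic
TRP	CD2	aromatic,hydrophobic
TRP	NE1	aromatic,donor
TRP	CE2	aromatic
TRP	CE3	aromatic,hydrophobic
TRP	CZ2	aromatic,hydrophobic
TRP	CZ3	aromatic,hydrophobic
TRP	CH2	aromatic,hydrophobic
TYR	N	donor
TYR	CA	-
TYR	C	-
TYR	O	acceptor
TYR	OXT	acceptor,negative
TYR	CB	hydrophobic
TYR	CG	aromatic,hydrophobic
TYR	CD1	aromatic,hydrophobic
TYR	CD2	aromatic,hydrophobic
TYR	CE1	aromatic,hydrophobic
TYR	CE2	aromatic,hydrophobic
TYR	CZ	aromatic
TYR	OH	acceptor,donor
VAL	N	donor
VAL	CA	-
VAL	C	-
VAL	O	acceptor
VAL	OXT	acceptor,negative
VAL	CB	hydrophobic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
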