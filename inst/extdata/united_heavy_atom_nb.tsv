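# united_heavy_atom_nb.tsv -- bundled non-bonded parameter table
# In-house united-charge heavy-atom set: hydrogen partial charges are
# folded into their bonded heavy atom so that unprotonated PDB files can
# be parameterized directly; Lennard-Jones classes follow common
# all-atom force-field conventions. Per-residue charges sum exactly to
# the residue formal charge (ASP/GLU -1, LYS/ARG +1, others 0; neutral His).
# Columns: res atom q(e) epsilon(kcal/mol) rmin_half(Angstrom)
res	atom	q	epsilon	rmin_half
ALA	N	-0.16	0.2000	1.8500
ALA	CA	0.16	0.0200	2.2750
ALA	C	0.51	0.1100	2.0000
ALA	O	-0.51	0.1200	1.7000
ALA	CB	0.00	0.0800	2.0600
ARG	N	-0.16	0.2000	1.8500
ARG	CA	0.16	0.0200	2.2750
ARG	C	0.51	0.1100	2.0000
ARG	O	-0.51	0.1200	1.7000
ARG	CB	0.00	0.0550	2.1750
ARG	CG	0.00	0.0550	2.1750
ARG	CD	0.38	0.0550	2.1750
ARG	NE	-0.26	0.2000	1.8500
ARG	CZ	0.64	0.0700	2.0000
ARG	NH1	0.12	0.2000	1.8500
ARG	NH2	0.12	0.2000	1.8500
ASN	N	-0.16	0.2000	1.8500
ASN	CA	0.16	0.0200	2.2750
ASN	C	0.51	0.1100	2.0000
ASN	O	-0.51	0.1200	1.7000
ASN	CB	0.00	0.0550	2.1750
ASN	CG	0.55	0.0700	2.0000
ASN	OD1	-0.55	0.1200	1.7000
ASN	ND2	0.00	0.2000	1.8500
ASP	N	-0.16	0.2000	1.8500
ASP	CA	0.16	0.0200	2.2750
ASP	C	0.51	0.1100	2.0000
ASP	O	-0.51	0.1200	1.7000
ASP	CB	-0.10	0.0550	2.1750
ASP	CG	0.62	0.0700	2.0000
ASP	OD1	-0.76	0.1200	1.7000
ASP	OD2	-0.76	0.1200	1.7000
CYS	N	-0.16	0.2000	1.8500
CYS	CA	0.16	0.0200	2.2750
CYS	C	0.51	0.1100	2.0000
CYS	O	-0.51	0.1200	1.7000
CYS	CB	0.07	0.0550	2.1750
CYS	SG	-0.07	0.4500	2.0000
GLN	N	-0.16	0.2000	1.8500
GLN	CA	0.16	0.0200	2.2750
GLN	C	0.51	0.1100	2.0000
GLN	O	-0.51	0.1200	1.7000
GLN	CB	0.00	0.0550	2.1750
GLN	CG	0.00	0.0550	2.1750
GLN	CD	0.55	0.0700	2.0000
GLN	OE1	-0.55	0.1200	1.7000
GLN	NE2	0.00	0.2000	1.8500
GLU	N	-0.16	0.2000	1.8500
GLU	CA	0.16	0.0200	2.2750
GLU	C	0.51	0.1100	2.0000
GLU	O	-0.51	0.1200	1.7000
GLU	CB	0.00	0.0550	2.1750
GLU	CG	-0.10	0.0550	2.1750
GLU	CD	0.62	0.0700	2.0000
GLU	OE1	-0.76	0.1200	1.7000
GLU	OE2	-0.76	0.1200	1.7000
GLY	N	-0.16	0.2000	1.8500
GLY	CA	0.16	0.0550	2.1750
GLY	C	0.51	0.1100	2.0000
GLY	O	-0.51	0.1200	1.7000
HIS	N	-0.16	0.2000	1.8500
HIS	CA	0.16	0.0200	2.2750
HIS	C	0.51	0.1100	2.0000
HIS	O	-0.51	0.1200	1.7000
HIS	CB	0.09	0.0550	2.1750
HIS	CG	-0.05	0.0700	1.9924
HIS	ND1	-0.04	0.2000	1.8500
HIS	CD2	0.10	0.0700	1.9924
HIS	CE1	0.30	0.0700	1.9924
HIS	NE2	-0.40	0.2000	1.8500
ILE	N	-0.16	0.2000	1.8500
ILE	CA	0.16	0.0200	2.2750
ILE	C	0.51	0.1100	2.0000
ILE	O	-0.51	0.1200	1.7000
ILE	CB	0.00	0.0200	2.2750
ILE	CG1	0.00	0.0550	2.1750
ILE	CG2	0.00	0.0800	2.0600
ILE	CD1	0.00	0.0800	2.0600
LEU	N	-0.16	0.2000	1.8500
LEU	CA	0.16	0.0200	2.2750
LEU	C	0.51	0.1100	2.0000
LEU	O	-0.51	0.1200	1.7000
LEU	CB	0.00	0.0550	2.1750
LEU	CG	0.00	0.0200	2.2750
LEU	CD1	0.00	0.0800	2.0600
LEU	CD2	0.00	0.0800	2.0600
LYS	N	-0.16	0.2000	1.8500
LYS	CA	0.16	0.0200	2.2750
LYS	C	0.51	0.1100	2.0000
LYS	O	-0.51	0.1200	1.7000
LYS	CB	0.00	0.0550	2.1750
LYS	CG	0.00	0.0550	2.1750
LYS	CD	0.00	0.0550	2.1750
LYS	CE	0.31	0.0550	2.1750
LYS	NZ	0.69	0.2000	1.8500
MET	N	-0.16	0.2000	1.8500
MET	CA	0.16	0.0200	2.2750
MET	C	0.51	0.1100	2.0000
MET	O	-0.51	0.1200	1.7000
MET	CB	0.00	0.0550	2.1750
MET	CG	0.04	0.0550	2.1750
MET	SD	-0.09	0.4500	2.0000
MET	CE	0.05	0.0800	2.0600
PHE	N	-0.16	0.2000	1.8500
PHE	CA	0.16	0.0200	2.2750
PHE	C	0.51	0.1100	2.0000
PHE	O	-0.51	0.1200	1.7000
PHE	CB	0.00	0.0550	2.1750
PHE	CG	0.00	0.0700	1.9924
PHE	CD1	0.00	0.0700	1.9924
PHE	CD2	0.00	0.0700	1.9924
PHE	CE1	0.00	0.0700	1.9924
PHE	CE2	0.00	0.0700	1.9924
PHE	CZ	0.00	0.0700	1.9924
PRO	N	-0.29	0.2000	1.8500
PRO	CA	0.11	0.0200	2.2750
PRO	C	0.51	0.1100	2.0000
PRO	O	-0.51	0.1200	1.7000
PRO	CB	0.00	0.0550	2.1750
PRO	CG	0.00	0.0550	2.1750
PRO	CD	0.18	0.0550	2.1750
SER	N	-0.16	0.2000	1.8500
SER	CA	0.16	0.0200	2.2750
SER	C	0.51	0.1100	2.0000
SER	O	-0.51	0.1200	1.7000
SER	CB	0.23	0.0550	2.1750
SER	OG	-0.23	0.1521	1.7700
THR	N	-0.16	0.2000	1.8500
THR	CA	0.16	0.0200	2.2750
THR	C	0.51	0.1100	2.0000
THR	O	-0.51	0.1200	1.7000
THR	CB	0.23	0.0200	2.2750
THR	OG1	-0.23	0.1521	1.7700
THR	CG2	0.00	0.0800	2.0600
TRP	N	-0.16	0.2000	1.8500
TRP	CA	0.16	0.0200	2.2750
TRP	C	0.51	0.1100	2.0000
TRP	O	-0.51	0.1200	1.7000
TRP	CB	0.00	0.0550	2.1750
TRP	CG	-0.03	0.0700	1.9924
TRP	CD1	0.15	0.0700	1.9924
TRP	CD2	0.01	0.0700	1.9924
TRP	NE1	-0.29	0.2000	1.8500
TRP	CE2	0.13	0.0700	1.9924
TRP	CE3	0.00	0.0700	1.9924
TRP	CZ2	0.00	0.0700	1.9924
TRP	CZ3	0.00	0.0700	1.9924
TRP	CH2	0.03	0.0700	1.9924
TYR	N	-0.16	0.2000	1.8500
TYR	CA	0.16	0.0200	2.2750
TYR	C	0.51	0.1100	2.0000
TYR	O	-0.51	0.1200	1.7000
TYR	CB	0.00	0.0550	2.1750
TYR	CG	0.00	0.0700	1.9924
TYR	CD1	0.00	0.0700	1.9924
TYR	CD2	0.00	0.0700	1.9924
TYR	CE1	0.00	0.0700	1.9924
TYR	CE2	0.00	0.0700	1.9924
TYR	CZ	0.11	0.0700	1.9924
TYR	OH	-0.11	0.1521	1.7700
VAL	N	-0.16	0.2000	1.8500
VAL	CA	0.16	0.0200	2.2750
VAL	C	0.51	0.1100	2.0000
VAL	O	-0.51	0.1200	1.7000
VAL	CB	0.00	0.0200	2.2750
VAL	CG1	0.00	0.0800	2.0600
VAL	CG2	0.00	0.0800	2.0600
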