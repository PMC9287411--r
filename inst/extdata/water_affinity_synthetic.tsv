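# water_affinity_synthetic.tsv -- SYNTHETIC water-affinity hydropathy
# scale: an affine rescaling of Kyte-Doolittle onto [0, 3] with the
# orientation H = 0.0 at the purely hydrophobic end and higher H more
# hydrophilic (H = (4.5 - KD)/3). It is a stand-in with the same
# orientation and range conventions as MD-derived water-orientation
# scales; class thresholds 1.3/1.7 are calibrated to this scale.
res	H
ALA	0.9
ARG	3.0
ASN	2.6667
ASP	2.6667
CYS	0.6667
GLN	2.6667
GLU	2.6667
GLY	1.6333
HIS	2.5667
ILE	0.0
LEU	0.2333
LYS	2.8
MET	0.8667
PHE	0.5667
PRO	2.0333
SER	1.7667
THR	1.7333
TRP	1.8
TYR	1.9333
VAL	0.1
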