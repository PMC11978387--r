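# Per-residue interface propensity ("stickiness") scale from Levy, De &
# Teichmann (2012) PNAS 109:20461, supplementary data. Unitless; positive
# values mark interaction-prone residue types.
residue_name,stickiness
ALA,0.0062
CYS,1.0372
ASP,-0.7485
GLU,-0.7893
PHE,1.2727
GLY,-0.1771
HIS,0.1204
ILE,1.1109
LYS,-1.1806
LEU,0.9138
MET,1.0124
ASN,-0.2693
PRO,-0.1799
GLN,-0.4114
ARG,-0.0876
SER,0.1376
THR,0.1031
VAL,0.7599
TRP,0.7925
TYR,0.8806
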