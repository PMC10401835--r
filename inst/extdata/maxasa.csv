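residue,maxasa
ALA,129.00
ARG,274.00
ASN,195.00
ASP,193.00
CYS,167.00
GLU,223.00
GLN,225.00
GLY,104.00
HIS,224.00
ILE,197.00
LEU,201.00
LYS,236.00
MET,224.00
PHE,240.00
PRO,159.00
SER,155.00
THR,172.00
TRP,285.00
TYR,263.00
VAL,174.00
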