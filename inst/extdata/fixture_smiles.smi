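CC ethane
CCO ethanol
CC(C)O isopropanol
CCN ethylamine
CCOC ethyl_methyl_ether
CC(=O)C acetone
CC(=O)O acetic_acid
CC(=O)N acetamide
CC#N acetonitrile
CC=C propene
CCC#C but-1-yne
CC=O acetaldehyde
NCCO ethanolamine
CNC dimethylamine
CCS ethanethiol
CSC dimethyl_sulfide
CCCl chloroethane
CCBr bromoethane
CCI iodoethane
CC(C)C isobutane
C1CCCCC1 cyclohexane
C1CCOC1 tetrahydrofuran
CCC(=O)OC methyl_propanoate
CCNCC diethylamine
OCC(O)CO glycerol
c1ccccc1 benzene
Cc1ccccc1 toluene
c1ccncc1 pyridine
Oc1ccccc1 phenol
Nc1ccccc1 aniline
c1ccoc1 furan
c1cc[nH]c1 pyrrole
c1ccsc1 thiophene
c1ccc2ccccc2c1 naphthalene
CC(N)C(=O)O alanine
O water
OP(=O)(O)O phosphoric_acid
CS(C)(=O)=O dimethyl_sulfone
CCCC butane
COc1ccccc1 anisole
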