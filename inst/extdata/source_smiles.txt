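# Bundled molecule source list for desk-scale corpus generation.
# Kekule-form SMILES, one per line, no stereochemistry.  Chosen to cover
# small and medium molecules (DeepSMILES label lengths spanning several of
# the evaluation length bins), rings of size >= 5, heteroaromatics, fused
# systems and bracket atoms (charged nitro groups, isotopes).
CCO
CCN
CC=O
CCC(=O)O
CC(C)O
CC(C)N
CCOC(C)=O
CC(=O)NC1=CC=C(O)C=C1
CC(=O)OC1=CC=CC=C1C(=O)O
CC(C)CC1=CC=C(C=C1)C(C)C(=O)O
CN1C=NC2=C1C(=O)N(C)C(=O)N2C
C1=CC=C(C=C1)C(=O)O
C1=CC=C(C=C1)O
C1=CC=C(C=C1)N
C1=CC=C(C=C1)C=O
C1=CC=C2C(=C1)C=CC=C2
C1=CC=C2C(=C1)NC=C2
C1=CC2=CC=CC=C2C=C1
C1CCCCC1
C1CCCC1
C1CCNCC1
C1CCOC1
C1CCNC1
C1COCCN1
C1CCC(CC1)O
C1CCC(CC1)N
C1=CN=CC=C1
C1=CC=NC=C1C
C1=CN=CN1
C1=CSC=C1
C1=COC=C1
C1=CC=C(C=C1)[N+](=O)[O-]
CC1=CC=C(C=C1)[N+](=O)[O-]
CC1=CC=CC=C1N
CC1=CC=CC=C1O
COC1=CC=CC=C1
COC1=CC=C(C=C1)C=O
CC(=O)C1=CC=CC=C1
FC1=CC=CC=C1
ClC1=CC=CC=C1
BrC1=CC=CC=C1
CC1=CC(=O)NC(=O)N1
CC1=NC=CN1C
CCC1=CC=CC=C1
CCOC(=O)C1=CC=CC=C1
NC(=O)C1=CC=CC=C1
OCC1=CC=CC=C1
OC1=CC=C(C=C1)C(=O)O
NC1=CC=C(C=C1)S(=O)(=O)N
CN(C)C1=CC=C(C=C1)C=O
CC(C)(C)C1=CC=C(O)C=C1
CSC1=CC=CC=C1
N#CC1=CC=CC=C1
OC(=O)C1=CC=CC=C1O
OC(=O)C1=CC=C(C=C1)[N+](=O)[O-]
CC1=CC=C(C=C1)S(=O)(=O)O
NC1=NC2=CC=CC=C2N1
C1=CC=C(C=C1)C2=CC=CC=C2
C1=CC=C(C=C1)OC2=CC=CC=C2
C1=CC=C(C=C1)CC2=CC=CC=C2
CC(=O)NC1=CC=C(C=C1)OCC
CCN(CC)C(=O)C1=CC=CC=C1
COC1=CC=C(C=C1)CCN
CC(C)NCC(O)COC1=CC=CC=C1
CN1CCC(CC1)OC(=O)C1=CC=CC=C1
OC1=CC=C(C=C1)C2=CC=C(O)C=C2
CC1=CC=C(C=C1)C(=O)C2=CC=CC=C2
COC(=O)C1=CC=CC=C1N
CCOC(=O)CC1=CC=CC=C1
CC(C)NCC(O)COC1=CC=CC2=CC=CC=C12
CN1CCN(CC1)C1=CC=C(C=C1)OCC1=CC=CC=C1
CN(C)CCOC(C1=CC=CC=C1)C1=CC=CC=C1
CCOC(=O)C1=CC=C(C=C1)NC(=O)CN1CCN(CC1)CC1=CC=CC=C1
OC(=O)CCC(=O)NC1=CC=C(C=C1)OCC1=CC=C(Cl)C=C1
COC1=CC2=C(C=C1OC)C(=O)CC(C2)CC1CCN(CC1)CC1=CC=CC=C1
CC1=CC=C(C=C1)S(=O)(=O)NC(=O)NC1CCCCC1
CN(C)CCCN1C2=CC=CC=C2SC2=CC=C(Cl)C=C12
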