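# Attachable substituent fragments (patent-style R groups), one SMILES
# fragment per line.  Each entry, attached through a single bond at an atom
# with a free valence, yields a parseable SMILES.  The list is swappable:
# pass a different file to substituent_pools() to use a larger inventory.
C
CC
CCC
C(C)C
C(C)(C)C
CCCC
O
OC
OCC
N
NC
N(C)C
F
Cl
Br
I
C#N
C(F)(F)F
C(=O)O
C(=O)OC
C(=O)N
C(=O)C
S
SC
S(=O)(=O)C
S(=O)(=O)N
[N+](=O)[O-]
OC(F)(F)F
C=C
C#C
c1ccccc1
Cc1ccccc1
Oc1ccccc1
c1ccncc1
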