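CC(=O)N(C)Cc1ccccc1
CC(=O)N(Cc1ccccc1)Cc1ccccc1
CC(=O)N(Cc1ccccc1)c1cccnc1
CC(C)C(=O)N(Cc1ccccc1)c1ccc(C(F)(F)F)cc1
CC(C)C(=O)N(Cc1ccccc1)c1ccc(O)cc1
CC(C)C(=O)N1CCCCC1
CC(C)N(Cc1ccccc1)C(=O)C1CC1
CC(C)N(Cc1ccccc1)C(=O)Cc1ccccc1
CC(C)N(Cc1ccccc1)C(=O)c1ccc(F)cc1
CC(C)NC(=O)c1ccccc1
CC(C)Nc1ccnc(-c2ccc(C(F)(F)F)cc2)n1
CC(C)Nc1ccnc(-c2ccc(Cl)cc2)n1
CC(C)Nc1ccnc(-c2ccc(F)cc2)n1
CC(C)Nc1ccnc(C(C)C)n1
CC(C)Nc1ccnc(CCS)n1
CC(C)Nc1ccnc(CCc2ccccc2)n1
CC(C)Nc1nccc(-c2ccccc2)n1
CC(C)Nc1nccc(C2CC2)n1
CC(C)Nc1nccc(CC#N)n1
CC(C)c1cc2ccccc2[nH]1
CC(C)c1cccc(C(=O)O)c1
CC(C)c1ccnc(NCCO)n1
CC(C)c1ccnc(NCCS)n1
CC(C)c1ccnc(Nc2ccc(Cl)cc2)n1
CC(C)c1nccc(Nc2ccc(F)cc2)n1
CC(C)c1nccc(Nc2ccccc2)n1
CCC(=O)N(CC#N)Cc1ccccc1
CCC(=O)N(CCc1ccccc1)Cc1ccccc1
CCC(=O)N(Cc1ccccc1)C(C)C
CCC(=O)N(Cc1ccccc1)C1CCCCC1
CCC(=O)N(Cc1ccccc1)Cc1ccccc1
CCCC(=O)N(CCO)Cc1ccccc1
CCCC(=O)N(Cc1ccccc1)Cc1ccccc1
CCCN(Cc1ccccc1)C(=O)c1ccc(Cl)cc1
CCCN(Cc1ccccc1)C(C)=O
CCCNC(=O)c1ccc2[nH]ccc2c1
CCCNC(=O)c1ccco1
CCCNc1ccnc(-c2ccc(Cl)cc2)n1
CCCNc1ccnc(-c2ccccc2)n1
CCCNc1ccnc(CC(N)=O)n1
CCCNc1ccnc(CCC)n1
CCCNc1nccc(-c2ccc(Cl)cc2)n1
CCCNc1nccc(-c2ccc(OC)cc2)n1
CCCNc1nccc(C)n1
CCCNc1nccc(CC#N)n1
CCCNc1nccc(CCOC)n1
CCCc1cc2ccccc2[nH]1
CCCc1ccnc(NC(C)C)n1
CCCc1ccnc(NC)n1
CCCc1ccnc(NCC(N)=O)n1
CCCc1ccnc(NCCO)n1
CCCc1ccnc(NCCOC)n1
CCCc1ccnc(NCCc2ccccc2)n1
CCCc1ccnc(Nc2ccc(O)cc2)n1
CCCc1nccc(NC(C)C)n1
CCCc1nccc(NCCc2ccccc2)n1
CCCc1nccc(Nc2ccc(OC)cc2)n1
CCCc1nccc(Nc2ccccc2)n1
CCN(CC)CCC(=O)N1CCCCC1
CCN(CC)CCN(Cc1ccccc1)C(=O)CCO
CCN(CC)CCN(Cc1ccccc1)C(=O)c1ccncc1
CCN(CC)CCNc1ccnc(-c2ccc(Cl)cc2)n1
CCN(CC)CCNc1nccc(CCO)n1
CCN(CC)CCNc1ncnc2ccccc12
CCN(CC)CCc1ccnc(NCCO)n1
CCN(CC)CCc1ccnc(NCCOC)n1
CCN(CC)CCc1ccnc(Nc2ccc(C(F)(F)F)cc2)n1
CCN(CC)CCc1ccnc(Nc2ccc(O)cc2)n1
CCN(CC)CCc1nccc(NCC#N)n1
CCN(CC)CCc1nccc(Nc2ccc(C(F)(F)F)cc2)n1
CCN(CC)CCc1nccc(Nc2ccc(OC)cc2)n1
CCN(CC)CCc1nccc(Nc2ccncc2)n1
CCN(Cc1ccccc1)C(=O)C(C)C
CCN(Cc1ccccc1)C(=O)C1CC1
CCN(Cc1ccccc1)C(=O)c1ccc(C(F)(F)F)cc1
CCN(Cc1ccccc1)C(=O)c1ccncc1
CCN(Cc1ccccc1)C(C)=O
CCNC(=O)/C=C/c1ccccc1
CCNc1ccnc(CC#N)n1
CCNc1nccc(-c2ccc(C(F)(F)F)cc2)n1
CCNc1nccc(CCOC)n1
CCNc1nccc(Cc2ccccc2)n1
CCc1ccnc(NCCO)n1
CCc1ccnc(NCCOC)n1
CCc1ccnc(Nc2ccccc2)n1
CCc1ccnc(Nc2ccncc2)n1
CCc1nccc(Nc2ccc(Cl)cc2)n1
CN(Cc1ccccc1)C(=O)CC(N)=O
CN(Cc1ccccc1)C(=O)c1ccncc1
CNc1ccnc(-c2ccc(C(F)(F)F)cc2)n1
CNc1ccnc(CCO)n1
CNc1ccnc(CCS)n1
CNc1ccnc(CCc2ccccc2)n1
COCCC(=O)N(CC#N)Cc1ccccc1
COCCC(=O)N(CCc1ccccc1)Cc1ccccc1
COCCC(=O)N(Cc1ccccc1)C1CCCCC1
COCCC(=O)N(Cc1ccccc1)c1ccc(C(F)(F)F)cc1
COCCC(=O)N(Cc1ccccc1)c1ccc(Cl)cc1
COCCC(=O)N(Cc1ccccc1)c1ccc(O)cc1
COCCC(=O)N(Cc1ccccc1)c1ccccc1
COCCC(=O)N1CCCCC1
COCCN(Cc1ccccc1)C(=O)C1CC1
COCCN(Cc1ccccc1)C(=O)CC#N
COCCN(Cc1ccccc1)C(=O)c1cccnc1
COCCN(Cc1ccccc1)C(=O)c1ccncc1
COCCNc1ccnc(CCS)n1
COCCNc1nccc(-c2ccc(Cl)cc2)n1
COCCNc1nccc(-c2cccnc2)n1
COCCNc1nccc(C)n1
COCCNc1nccc(CC#N)n1
COCCNc1nccc(CCOC)n1
COCCc1ccnc(NC(C)C)n1
COCCc1cnn(-c2ccccc2)c1
COCCc1nccc(NCC(N)=O)n1
COCCc1nccc(Nc2ccccc2)n1
COc1ccc(-c2ccnc(NC3CCCCC3)n2)cc1
COc1ccc(-c2ccnc(NCCO)n2)cc1
COc1ccc(-c2ccnc(NCCc3ccccc3)n2)cc1
COc1ccc(-c2ccnc(NCc3ccccc3)n2)cc1
COc1ccc(-c2ccnc(Nc3cccnc3)n2)cc1
COc1ccc(-c2nccc(NC3CC3)n2)cc1
COc1ccc(-c2nccc(NCCc3ccccc3)n2)cc1
COc1ccc(C(=O)N(CC#N)Cc2ccccc2)cc1
COc1ccc(C(=O)N(CCO)Cc2ccccc2)cc1
COc1ccc(C(=O)N(CCc2ccccc2)Cc2ccccc2)cc1
COc1ccc(C(=O)N(Cc2ccccc2)c2ccc(F)cc2)cc1
COc1ccc(N(Cc2ccccc2)C(=O)CC(N)=O)cc1
COc1ccc(NC(=O)/C=C/c2ccccc2)cc1
COc1ccc(Nc2ccnc(-c3ccc(OC)cc3)n2)cc1
COc1ccc(Nc2ccnc(CCc3ccccc3)n2)cc1
COc1ccc(Nc2nccc(C)n2)cc1
COc1ccc(Nc2nccc(CC#N)n2)cc1
Cc1ccc(C(=O)Nc2ccccc2)cc1
Cc1ccnc(NC2CCCCC2)n1
Cc1ccnc(Nc2ccccc2)n1
Cc1ccnc(Nc2cccnc2)n1
Cc1nccc(NCc2ccccc2)n1
Cc1nccc(Nc2ccccc2)n1
Clc1ccc(-c2ccnc(NC3CCCCC3)n2)cc1
Clc1ccc(-c2nccc(NCCc3ccccc3)n2)cc1
Clc1ccc(N2CCN(c3ccncn3)CC2)cc1
FC(F)(F)c1ccc(-c2ccnc(Nc3ccc(Cl)cc3)n2)cc1
FC(F)(F)c1ccc(-c2ccnc(Nc3ccncc3)n2)cc1
FC(F)(F)c1ccc(-n2cnc3ccccc32)cc1
FC(F)(F)c1ccc(Nc2ccnc(C3CC3)n2)cc1
FC(F)(F)c1ccc(Nc2nccc(-c3ccc(Cl)cc3)n2)cc1
FC(F)(F)c1ccc(Nc2nccc(-c3cccnc3)n2)cc1
FC(F)(F)c1ccc(Nc2nccc(C3CC3)n2)cc1
FC(F)(F)c1ccc(Nc2nccc(C3CCCCC3)n2)cc1
Fc1ccc(-c2ccnc(NCCS)n2)cc1
Fc1ccc(-c2nccc(NC3CC3)n2)cc1
Fc1ccc(-c2nccc(Nc3ccc(C(F)(F)F)cc3)n2)cc1
Fc1ccc(Nc2nccc(-c3ccc(C(F)(F)F)cc3)n2)cc1
Fc1ccc(Nc2nccc(-c3ccccc3)n2)cc1
Fc1ccc(Nc2nccc(CCS)n2)cc1
N#CCC(=O)N(Cc1ccccc1)c1ccc(C(F)(F)F)cc1
N#CCC(=O)N(Cc1ccccc1)c1ccc(Cl)cc1
N#CCC(=O)N(Cc1ccccc1)c1ccccc1
N#CCN(Cc1ccccc1)C(=O)c1ccc(O)cc1
N#CCNS(=O)(=O)c1ccccc1
N#CCNc1ccnc(-c2ccc(C(F)(F)F)cc2)n1
N#CCNc1ccnc(-c2cccnc2)n1
N#CCNc1ccnc(CCS)n1
N#CCNc1ccnc(Cc2ccccc2)n1
N#CCNc1nccc(C2CC2)n1
N#CCc1cc2ccccc2[nH]1
N#CCc1ccnc(NC2CC2)n1
N#CCc1ccnc(NC2CCCCC2)n1
N#CCc1ccnc(Nc2ccncc2)n1
N#CCc1nccc(NCCc2ccccc2)n1
N#CCc1nccc(Nc2ccc(C(F)(F)F)cc2)n1
NC(=O)CC(=O)N(Cc1ccccc1)c1ccc(O)cc1
NC(=O)CN(Cc1ccccc1)C(=O)c1ccc(C(F)(F)F)cc1
NC(=O)CN(Cc1ccccc1)C(=O)c1ccc(O)cc1
NC(=O)CNc1ccnc(CCS)n1
NC(=O)CNc1nccc(C2CC2)n1
NC(=O)CNc1nccc(Cc2ccccc2)n1
NC(=O)Cc1cc2ccccc2[nH]1
NC(=O)Cc1ccnc(NC2CC2)n1
NC(=O)Cc1ccnc(Nc2ccc(O)cc2)n1
NC(=O)Cc1cnn(-c2ccccc2)c1
NC(=O)Cc1nccc(NCCO)n1
NC(=O)Cc1nccc(Nc2ccccc2)n1
O=C(C1CC1)N(CCc1ccccc1)Cc1ccccc1
O=C(C1CC1)N(Cc1ccccc1)Cc1ccccc1
O=C(C1CC1)N(Cc1ccccc1)c1cccnc1
O=C(C1CCCCC1)N(Cc1ccccc1)c1ccncc1
O=C(CCO)N(Cc1ccccc1)C1CC1
O=C(CCO)N(Cc1ccccc1)c1ccc(C(F)(F)F)cc1
O=C(CCc1ccccc1)N(Cc1ccccc1)c1ccncc1
O=C(Cc1ccccc1)N(CCc1ccccc1)Cc1ccccc1
O=C(NCCc1ccccc1)c1ccccc1
O=C(NCCc1ccccc1)c1ccco1
O=C(Nc1ccc(Cl)cc1)c1ccccc1
O=C(Nc1ccc(F)cc1)c1ccc2[nH]ccc2c1
O=C(Nc1ccccc1)c1ccc(-c2ccc(Cl)cc2)cc1
O=C(Nc1ccccc1)c1ccc(-c2ccc(F)cc2)cc1
O=C(Nc1ccccc1)c1ccccc1
O=C(Nc1ccccc1)c1ccco1
O=C(Nc1ccncc1)c1ccc2[nH]ccc2c1
O=C(Nc1ccncc1)c1ccco1
O=C(O)c1cccc(-c2ccccc2)c1
O=C(O)c1cccc(C2CCCCC2)c1
O=C(c1ccc(C(F)(F)F)cc1)N(Cc1ccccc1)C1CC1
O=C(c1ccc(C(F)(F)F)cc1)N(Cc1ccccc1)Cc1ccccc1
O=C(c1ccc(C(F)(F)F)cc1)N(Cc1ccccc1)c1ccccc1
O=C(c1ccc(C(F)(F)F)cc1)N1CCCCC1
O=C(c1ccc(Cl)cc1)N(Cc1ccccc1)c1ccc(C(F)(F)F)cc1
O=C(c1ccc(Cl)cc1)N(Cc1ccccc1)c1ccc(F)cc1
O=C(c1ccc(F)cc1)N(Cc1ccccc1)C1CC1
O=C(c1ccc(F)cc1)N(Cc1ccccc1)c1ccc(O)cc1
O=C(c1ccc(O)cc1)N(Cc1ccccc1)c1cccnc1
O=C(c1ccccc1)N(CCc1ccccc1)Cc1ccccc1
O=C(c1ccccc1)N(Cc1ccccc1)c1ccc(C(F)(F)F)cc1
O=C(c1cccnc1)N(Cc1ccccc1)C1CCCCC1
O=C(c1cccnc1)N(Cc1ccccc1)c1ccc(C(F)(F)F)cc1
O=S(=O)(Nc1ccccc1)c1ccccc1
O=S(=O)(Nc1ccncc1)c1ccccc1
OCCNc1ccnc(-c2cccnc2)n1
OCCNc1ccnc(C2CCCCC2)n1
OCCNc1nccc(-c2ccc(F)cc2)n1
OCCc1cnn(-c2ccccc2)c1
OCCc1nccc(Nc2ccc(F)cc2)n1
Oc1ccc(-c2ccnc(NC3CC3)n2)cc1
Oc1ccc(-c2ccnc(Nc3ccncc3)n2)cc1
Oc1ccc(-c2nccc(NCc3ccccc3)n2)cc1
Oc1ccc(-c2nccc(Nc3ccncc3)n2)cc1
Oc1ccc(Nc2ccnc(-c3ccc(O)cc3)n2)cc1
Oc1ccc(Nc2nccc(-c3ccc(F)cc3)n2)cc1
Oc1ccc(Nc2nccc(C3CC3)n2)cc1
Oc1ccc(Nc2nccc(Cc3ccccc3)n2)cc1
SCCNc1nccc(-c2ccccc2)n1
SCCNc1nccc(CCS)n1
SCCNc1ncnc2ccccc12
SCCc1ccnc(Nc2ccncc2)n1
c1cc(C2CCCCC2)nc(NC2CCCCC2)n1
c1cc(N2CCN(C3CCCCC3)CC2)ncn1
c1cc(NC2CCCCC2)nc(C2CC2)n1
c1cc(Nc2ccnc(-c3ccncc3)n2)ccn1
c1cc(Nc2nccc(C3CCCCC3)n2)ccn1
c1ccc(-n2cc(C3CCCCC3)cn2)cc1
c1ccc(CCNc2ccnc(CCc3ccccc3)n2)cc1
c1ccc(CCNc2nccc(C3CC3)n2)cc1
c1ccc(CCNc2ncnc3ccccc23)cc1
c1ccc(CCn2cnc3ccccc32)cc1
c1ccc(CNc2nccs2)cc1
c1ccc(CNc2ncnc3ccccc23)cc1
c1ccc(Cc2cc3ccccc3[nH]2)cc1
c1ccc(Cc2ccnc(Nc3ccncc3)n2)cc1
c1ccc(Cc2nccc(Nc3ccccc3)n2)cc1
c1ccc(N2CCN(c3ccncn3)CC2)cc1
c1ccc(Nc2ccnc(C3CCCCC3)n2)cc1
c1ccc(Nc2nccc(-c3ccncc3)n2)cc1
c1ccc(Nc2nccc(C3CC3)n2)cc1
c1ccc(Oc2ccccc2-c2ccncc2)cc1
c1ccc(Oc2ccccc2C2CC2)cc1
c1ccc2c(NC3CC3)ncnc2c1
c1ccc2c(c1)ncn2C1CCCCC1
c1cncc(-c2cc3ccccc3[nH]2)c1
c1cncc(-c2nccc(Nc3ccncc3)n2)c1
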