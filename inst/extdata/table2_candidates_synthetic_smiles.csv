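compound_id,name,smiles
ZINC26966472,Cacospongionolide B,CC1(C)CCCC2(C)C1CCC1(C)C2CCC1C1=CC(=O)OC1O
ZINC3871891,Carnosol,CC(C)c1cc2c(c(O)c1O)C1CCC(C)(C)CC1C(=O)O2
ZINC2585546,Dihydrotanshinone I,CC1COc2c1C(=O)C(=O)c1c2ccc2c1cccc2C
ZINC58576553,Epoxyazadiradione,CC1(C)C2CCC3(C)C(CC(=O)C4(C)C3C(=O)C=C4c3ccoc3)C2OC1=O
ZINC29134693,Farnesiferol B,O=C1C=Cc2ccc(OCC3=CCCC4(C)CCCC(C)(C)C34)cc2O1
ZINC4097720,Friedelin,CC1C(=O)CCC2(C)C1CCC1(C)C2CCC2(C)C1CCC1(C)C2CCC1(C)C
ZINC72123265,Fuscoside B,CC(C)C1CCC2(C)CCCC(C)(COC3OCC(O)C(O)C3O)C2C1
ZINC3860467,Gibberellic acid,CC1(O)CCC23CC1CC2C1(C)C(O)C=CC2(OC1=O)C3CC(C(=O)O)C2=C
ZINC3875454,Gliotoxin,CN1C(=O)C2(CO)SSC1(Cc1ccccc1)C(=O)N2C
ZINC95911093,Hinokitiol,CC(C)C1=CC(=O)C(O)=CC=C1
ZINC100090140,Neurolenin B,CC1=CCC(OC(C)=O)C(=O)C=C(C)CC2OC(=O)C(=C)C12
ZINC3874657,Penicillic acid,CC(=C)C1(O)C=C(OC)C(=O)O1
ZINC34383300,Preussomerin C,OC1CC2(Oc3cccc4c3C(=O)C=CC24)Oc2cccc3c2C1(O)C=CC3=O
ZINC2558154,Tanshinone I,Cc1coc2c1C(=O)C(=O)c1c2ccc2c1cccc2C
ZINC1650576,Tanshinone IIA,Cc1coc2c1C(=O)C(=O)c1c2ccc2c1CCCC2(C)C
ZINC6483512,Triptolide,CC(C)C12OC1C1OC13C1OC1(CC3O)C1(C)CCC3(C2)OC(=O)C3=C1
ZINC31356858,Ursolic acid,CC1CCC2(C(=O)O)CCC3(C)C(=CC2C1C)C1(C)CCC2(C)CCC(O)C(C)(C)C2C1CC3
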