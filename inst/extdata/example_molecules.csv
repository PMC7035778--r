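smiles,value,ring_fraction
C1CCCCC1,3.13415820392542,
C(N)CCCCCCCCC(Cl),4.98459211013296,
c1cc(C(=O)O)ncc1,4.1447038714097,0.666666666666667
C1CCC(O)CC1,3.82177472291699,
C1CCCCC1,3.04652784041362,1
CCC,1.49597837041607,
CCCCCCCCCC,4.88404415275916,0
CCCC(Br)C,3.36873881919163,0
c1ccc(CCCC)cc1,,0.6
CC(=O),1.70806553119326,
CCCCCCC,3.70107168402787,
c1ccccc1,,1
c1ccc(CCCCCC)cc1,5.97140959138777,0.5
c1cc(Br)ncc1,3.15455379550083,
CCC(N),1.23024624078843,
CCCCCC(Br)CC(N),4.59061178745038,0
C(N)C(OC)CCC(Br),4.36996725308477,
C(Cl)C,1.55870599310535,
CCCCC(Cl)C(F)CC(C(=O)O)CC,7.18649503119547,
C(N)C(=O)CCCCC,3.94883840019978,0
C1CCCCC1,3.1010171423484,1
c1c(C(=O)O)cnc(Br)c1,,0.6
c1c(Cl)cnc(C#N)c1,,0.666666666666667
c1cc(F)cc(Br)c1,3.6832177740018,
c1c(F)cnc(C(=O)O)c1,4.00320988153811,
c1cc(Cl)cc(Br)c1,4.21154749995036,0.75
C1CCCCC1,2.96430623196611,
CCCCCCCCCC,,0
c1c(O)cnc(N)c1,2.41756948486406,
c1cc(Br)cc(C#N)c1,4.01345387976676,0.666666666666667
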