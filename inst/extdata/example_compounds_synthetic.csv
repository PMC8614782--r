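id,name,smiles,soac
c01,alpha-tocopherol,CC1=C(C(=C2CCC(OC2=C1C)(C)CCCC(C)CCCC(C)CCCC(C)C)C)O,1.0
c02,phenol,Oc1ccccc1,0.004
c03,hydroquinone,Oc1ccc(O)cc1,0.12
c04,catechol,Oc1ccccc1O,0.09
c05,resorcinol,Oc1cccc(O)c1,0.02
c06,trolox-like chromanol,CC1=C(O)c2c(C)c(C)c(C)c(C)c2OC1,0.8
c07,trans-beta-ionone,CC1=C(C(CCC1)(C)C)/C=C/C(=O)C,0.35
c08,sorbic acid,C/C=C/C=C/C(=O)O,0.05
c09,retinol-like tetraene,CC1=C(C(CCC1)(C)C)/C=C/C(=C/C=C/C(=C/CO)/C)/C,3.5
c10,lycopene fragment,CC(=CCC/C(=C/C=C/C(=C/C=C/C=C(\C)/C=C/C=C(\C)/C)/C)/C)C,18.0
c11,ascorbic-acid-like enediol,OCC(O)C1OC(=O)C(O)=C1O,0.3
c12,indole,c1ccc2[nH]ccc2c1,0.07
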