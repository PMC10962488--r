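"smiles","docking_score"
"C1CCCCC1c2ccncc2C",-7.9
"CC(C)CCNF",-6.221
"c1ccc(C)cc1C#N",-5.365
"CCCCCNc1ccncc1c2ccncc2C(=O)N",-6.178
"CCCCCCC(=O)N",-6.851
"c1ccc(C)cc1c2ccccc2Cl",-7.776
"c1ccncc1C(=O)N",-6.138
"CCCCCOCC(C)c1ccncc1O",-6.29
"c1ccc(C)cc1CN",-7.826
"c1ccsc1CCSO",-5.473
"c1ccncc1CN",-6.475
"CCCCO",-6.984
"c1ccncc1C",-7.132
"CCCCCOCOCCCSCl",-7.23
"c1ccncc1c2ccncc2COCCN",-6.224
"c1ccncc1CCNCC(C)F",-7.291
"CC(C)CCSCCOCl",-7.922
"CC(C)CN(C)CO",-5.286
"CCCCCCO",-5.006
"C1CCCCC1CO",-6.409
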