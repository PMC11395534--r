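O=c1[nH]cc(CCCI)c(=O)[nH]1 compound_40
ClCCCc1cnc(Cl)nc1Cl compound_41
Clc1ncc2c(n1)OCCC2 compound_42
COc1ncc(CCCCl)c(OC)n1 compound_43
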