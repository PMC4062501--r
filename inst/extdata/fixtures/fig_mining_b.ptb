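(S (PP-ARGM-DIS (IN In) (NN contrast)) (NP-ARG1 (NN mRNA) (VBG representing) (NN pAT) (NN 591/EGR2)) (VP (VBD was) (VP (RB-ARGM-NEG not) (VBN-PRED expressed) (PP-ARGM-LOC (IN in) (DT these) (NNS cells)))))
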