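(S (NP-ARG0 (NN T3)) (ADVP-ARGM-MNR (RB efficiently)) (VP (VBD-PRED induced) (NP-ARG1 (JJ erythroid) (NN differentiation)) (RB-ARGM-DIS thus) (S-ARGM-ADV (VP (VBG overcoming) (NP (DT the) (JJ v-erbA-mediated) (NN differentiation) (NN arrest))))) (PP-ARGM-LOC (IN in) (DT these) (NNS cells)))
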