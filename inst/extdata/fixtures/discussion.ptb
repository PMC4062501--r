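(S (NP (NP (JJ partial) (NN amino) (NN acid) (NNS sequences)) (VP (VBN obtained) (PP (IN from) (NP (JJ purified) (NN EBF))))) (VP (VBD were) (VP (VBN used) (S (VP (TO to) (VP (VB isolate) (NP (NP-ARG0 (NN cDNA) (NNS clones)) (SBAR (WHNP-R-ARG0 (WDT which)) (S (PP-ARGM-MNR (IN by) (NP (JJ multiple) (NNS criteria))) (VP (VBP-PRED encode) (NP-ARG1 (NN EBF))))))))))))
(NP (NP (NN Isolation)) (PP (IN of) (NP (NP-ARG0 (DT a) (JJ rel-related) (JJ human) (NN cDNA)) (SBAR (WHNP-R-ARG0 (WDT that)) (S (ADVP-ARGM-MNR (RB potentially)) (VP (VBZ-PRED encodes) (NP-ARG1 (NP (DT the) (JJ 65-kD) (NN subunit)) (PP (IN of) (NP (NN NF-kappa-B))))))))))
(S (SBAR-ARGM-ADV (IN Although) (S (NP (JJ lymphokine) (NNS genes)) (VP (VBP are) (VP (ADVP (RB coordinately)) (VBN regulated) (PP (IN upon) (NP (NN antigen) (NN stimulation))))))) (NP-ARG1 (PRP they)) (VP (VBP are) (VP (VBN-PRED regulated) (PP-ARG0 (IN by) (NP (DT the) (NNS mechanisms))))))
(S (ADVP (RB However)) (NP (NP (DT the) (JJ profound) (NN T-cell) (NN deficit)) (PP (IN of) (NP (NN nude-mice)))) (VP (VBZ indicates) (SBAR (IN that) (S (NP-ARG0 (DT the) (NN thymus)) (VP (VBZ is) (NP (NP (DT the) (RBS most) (JJ potent) (NN site)) (PP (IN for) (S (VP (VBG-PRED inducing) (NP-ARG1 (DT the) (NN expansion)) (ADVP-ARGM-MNR (FW per) (FW se)))))))))))
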