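(S (NP-ARG0 (NN Tax)) (VP (VBD-PRED activated) (NP-ARG1 (NN HTLV-1) (NN transcription)) (ADVP-ARGM-EXT (RB approximately) (RB 12-fold))))
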