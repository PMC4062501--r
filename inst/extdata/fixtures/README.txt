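Synthetic reconstructions of the worked example sentences used in the test
suite.  The source material prints syntactic paths and item sets, not trees;
these trees were reconstructed to be consistent with the printed paths and
item values wherever the printed values are mutually consistent.

fig_extent.ptb     extent-marker example ("approximately 12-fold" as a
                   sibling of the verb predicate).
fig_mining_a.ptb   rule-mining example (a): six gold arguments; all six
                   printed transactions (items and paths) are reproduced
                   exactly by extraction from this tree.
fig_mining_b.ptb   rule-mining example (b): four gold arguments.  The four
                   printed paths are mutually inconsistent (the ARGM-DIS path
                   implies the predicate's ancestor chain is VP-VP-S while
                   the ARG1 path implies VP-S, and two paths carry a VBD tag
                   although the predicate terminal is tagged VBN), so no tree
                   can realize all four.  This tree realizes the ARGM-DIS path
                   exactly; the three remaining paths differ from the printed
                   text only at those documented typo positions.  See
                   fig_mining_transactions.tsv for both versions.
discussion.ptb     four analysis sentences: the duplicate-argument example
                   ("cDNA clones" / "multiple criteria"), the
                   overlapping-argument example ("Isolation of a rel-related
                   human cDNA"), the long adverbial-clause example
                   ("Although lymphokine genes..."), and the candidate-pruning
                   error example ("the thymus").
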