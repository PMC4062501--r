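# srlkit

Constituent-by-constituent semantic role labeling for biomedical text, with
collective decoding and resource-saving preprocessing.

## What problem this solves

Sentences about biological processes are commonly summarized as
predicate–argument structures (PAS): a verb predicate plus the constituents
filling PropBank-style roles — core arguments `ARG0`–`ARG5`/`ARGX` (with
`R-`/`C-` variants) and adjuncts `ARGM-LOC`, `ARGM-TMP`, `ARGM-NEG`, and so
on.  Most labelers classify each parse-tree node independently, which lets
them assign the same core role twice or label two overlapping nodes — errors
that are impossible structures.  srlkit is for NLP researchers and
text-mining pipeline builders who want a labeler that (a) decodes all nodes
*jointly* under the structural constraints and (b) trains on a pruned
grounding set small enough to scale.

The model is log-linear with hard constraints.  For a tree with predicate
*p*, each grounding (node *i*, role *r*) scores
`s(i, r) = sum_j w_j f_j(i, p, r)` over sparse local features (syntactic
path, constituent type, position, voice, Collins head word, first/last words,
sub-categorization, context, combinations).  Decoding solves

```
max_y  sum_i s(i, y_i)      subject to
       |{i : y_i = r}| <= 1        for each core role r   (tree collective)
       y_i = NONE or y_j = NONE    whenever spans i, j overlap (path collective)
```

exactly, by branch-and-bound or lazy cutting-plane search (`NONE` scores 0).
Weights are learned with 1-best MIRA: `w += tau (Phi(gold) - Phi(pred))`,
`tau = min(C, (loss - margin)/||dPhi||^2)`, with weight averaging.  Before
training, a four-rule tree-pruning filter and four candidate identifiers
(mined association rules, word lists, marker patterns, a parse-path database)
shrink the node pool; their proposals also enter the model as
candidate-identification features.

## Worked example

```r
library(srlkit)

tree <- parse_ptb("(S (NP-ARG0 (NN IL4))
                     (VP (VBD-PRED induced)
                         (NP-ARG1 (JJ erythroid) (NN differentiation))
                         (PP-ARGM-LOC (IN in) (NP (DT these) (NNS cells)))))")[[1]]
tree
#> <srl_tree> 7 tokens, 13 nodes
#>   sentence: IL4 induced erythroid differentiation in these cells
#>   predicate: induced [induce] at token 1
#>   gold roles: ARG0=NP("IL4"), ARG1=NP("erythroid differentiation"), ARGM-LOC=PP("in these cells")

syntactic_path(tree, 2L, tree$pred)   # subject NP to the predicate terminal
#> NP > S < VP < VBD

apply_tpf(tree, prune_config())       # nodes surviving the pruning filter
#> [1]  2  6  9 11
```

Train the resource-saving collective configuration on a synthetic corpus and
score held-out sentences:

```r
train <- generate_corpus(gen_config(n_sentences = 120, seed = 42, signal = 0.95))
test  <- generate_corpus(gen_config(n_sentences = 40,  seed = 43, signal = 0.95))
model <- train_srl(train, config_resource_saving(seed = 1))
pred  <- label_corpus(model, test)
gold  <- lapply(test, gold_assignment)

rep <- conll_evaluate(gold, pred, gold_trees = test)
rep[rep$role %in% c("ARG0", "ARG1", "ARGM-LOC", "Overall"), ]
#>        role gold predicted correct precision recall      f
#> 1      ARG0   33        35      31     88.57  93.94  91.18
#> 2      ARG1   40        40      40    100.00 100.00 100.00
#> 6  ARGM-LOC   17        17      17    100.00 100.00 100.00
#> 11  Overall  141       140     135     96.43  95.74  96.09

pas_evaluate(gold, pred, gold_trees = test)
#>   role gold predicted correct precision recall  f
#> 1  PAS   40        40      34        85     85 85
```

Argument-wide rows count each argument separately (exact span + label);
the `PAS` row counts a whole structure only when every argument of its
predicate is exactly right — the stricter metric on which collective decoding
shows its advantage over per-node labeling (compare
`config_local()`).  A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","srl.R",package="srlkit"))')" \
    simulate --n 200 --seed 7 -o corpus.ptb
```

with subcommands `simulate`, `prune`, `mine-rules`, `train`, `label`,
`evaluate`.

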