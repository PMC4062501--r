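#' Default stop-word list for pruning rule 4
#'
#' A bundled list of English closed-class function words.  It excludes
#' personal and relative pronouns and every entry of the word-based candidate
#' identifier's lists (discourse, modal, negation words), because nodes
#' spanning those words are legitimate argument candidates.
#'
#' @param file optional path to a plain-text list (one word per line, `#`
#'   comments) overriding the bundled one.
#' @return a lower-cased character vector.
#' @export
default_stopwords <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "stopwords_en.txt", package = "srlkit",
                        mustWork = TRUE)
  x <- readLines(file, warn = FALSE)
  x <- trimws(x)
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}

#' Tree-pruning filter configuration
#'
#' @param rules subset of `1:4` selecting the enabled pruning rules.
#' @param stopwords word list for rule 4 (matched case-insensitively against
#'   single-token spans).
#' @return a `prune_config` list.
#' @export
prune_config <- function(rules = 1:4, stopwords = default_stopwords()) {
  stopifnot(all(rules %in% 1:4))
  structure(list(rules = as.integer(rules), stopwords = tolower(stopwords)),
            class = "prune_config")
}

#' Nodes removed by one pruning rule
#'
#' The four rules mark nodes that are unlikely to be arguments:
#' \enumerate{
#'   \item nodes whose span contains the verb-predicate token (the predicate
#'     terminal and everything on its path to the root);
#'   \item all terminal nodes;
#'   \item nodes that are their parent's only child (the root, having no
#'     parent, is never removable by this rule);
#'   \item nodes whose entire span, lower-cased, is a single stop-word.
#' }
#' Masks are computed on the intact tree; rules are idempotent and
#' order-independent.
#'
#' @param t an `srl_tree`.
#' @param rule_id one of 1, 2, 3, 4.
#' @param stopwords rule-4 word list.
#' @param pred predicate terminal index (defaults to the tree's).
#' @return integer vector of removed node indices.
#' @export
tpf_rule_mask <- function(t, rule_id, stopwords = default_stopwords(),
                          pred = t$pred) {
  if (!rule_id %in% 1:4) stop("unknown pruning rule id: ", rule_id)
  n <- seq_len(n_nodes(t))
  switch(as.character(rule_id),
    "1" = {
      if (is.na(pred)) return(integer(0))
      pt <- t$start[pred]
      n[t$start <= pt & t$end > pt]
    },
    "2" = n[is_terminal(t)],
    "3" = tpf_rule3(t),
    "4" = n[(t$end - t$start) == 1L &
              tolower(t$tokens[t$start + 1L]) %in% tolower(stopwords)])
}

# rule 3 needs its own loop; patch it in cleanly
tpf_rule3 <- function(t) {
  n <- seq_len(n_nodes(t))
  has_parent <- !is.na(t$parent)
  only <- vapply(n, function(i)
    has_parent[i] && length(t$children[[t$parent[i]]]) == 1L, logical(1))
  n[only]
}

#' Apply the tree-pruning filter
#'
#' Surviving nodes are all nodes minus the union of the enabled rules' masks.
#' The tree itself is left intact: pruning narrows the candidate pool, while
#' feature extraction still sees the full tree.
#'
#' @param t an `srl_tree`.
#' @param config a [prune_config()].
#' @param pred predicate terminal index (defaults to the tree's).
#' @return sorted integer vector of surviving node indices.
#' @examples
#' tr <- parse_ptb("(S (NP (DT the) (NN gene)) (VP (VBD-PRED induced)))")[[1]]
#' apply_tpf(tr, prune_config())
#' @export
apply_tpf <- function(t, config = prune_config(), pred = t$pred) {
  removed <- integer(0)
  for (r in config$rules)
    removed <- union(removed, tpf_rule_mask(t, r, config$stopwords, pred))
  setdiff(seq_len(n_nodes(t)), removed)
}
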