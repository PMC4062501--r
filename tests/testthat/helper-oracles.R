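# Shared fixtures and independent brute-force oracles used across the suite.

rand_corpus <- function(n, seed, ...) generate_corpus(gen_config(n, seed, ...))

# per-node brute-force re-statement of each pruning rule
brute_rule_mask <- function(t, rule, stopwords = default_stopwords()) {
  hits <- integer(0)
  for (i in seq_len(length(t$label))) {
    rm <- switch(as.character(rule),
      "1" = !is.na(t$pred) &&
        t$start[i] <= t$start[t$pred] && t$end[i] > t$start[t$pred],
      "2" = !is.na(t$word[i]),
      "3" = !is.na(t$parent[i]) && length(t$children[[t$parent[i]]]) == 1L,
      "4" = (t$end[i] - t$start[i]) == 1L &&
        tolower(t$tokens[t$start[i] + 1L]) %in% stopwords)
    if (rm) hits <- c(hits, i)
  }
  hits
}

# exhaustive association-rule enumeration over subsets of transactions
brute_rules <- function(transactions, min_support, min_confidence,
                        max_antecedent = 4L) {
  nT <- length(transactions)
  subsets <- function(x, kmax) {
    out <- list()
    for (k in seq_len(min(length(x), kmax)))
      out <- c(out, utils::combn(x, k, simplify = FALSE))
    out
  }
  cand <- unique(unlist(lapply(transactions, subsets, max_antecedent + 1L),
                        recursive = FALSE))
  cand <- lapply(cand, sort)
  cand <- unique(cand)
  supp <- function(set) mean(vapply(transactions, function(tr)
    all(set %in% tr), logical(1)))
  rows <- list()
  for (set in cand) {
    role <- set[startsWith(set, "ROLE(")]
    if (length(role) != 1L || length(set) < 2L) next
    ante <- setdiff(set, role)
    s_joint <- supp(set)
    if (s_joint + 1e-12 < min_support) next
    conf <- s_joint / supp(ante)
    if (conf + 1e-12 < min_confidence) next
    rows[[length(rows) + 1L]] <- sprintf(
      "%s=>%s@%.10f@%.10f", paste(ante, collapse = " & "),
      sub("^ROLE\\((.*)\\)$", "\\1", role), s_joint, conf)
  }
  if (!length(rows)) character(0) else sort(unlist(rows))
}

rule_keys <- function(rules) {
  if (!nrow(rules)) return(character(0))
  sort(sprintf("%s=>%s@%.10f@%.10f", rules$antecedent, rules$role,
               rules$support, rules$confidence))
}

# build a ground problem directly from a score matrix and spans
make_gp <- function(scores, start, end, roles = colnames(scores)) {
  n <- nrow(scores)
  ov <- outer(start, end, "<") & outer(end, start, ">")
  diag(ov) <- FALSE
  structure(list(tree = NULL, nodes = seq_len(n), roles = roles,
                 scores = scores, overlap = ov, start = start,
                 depth = rep(0L, n), feats = NULL, ci_roles = NULL,
                 use_ci = FALSE),
            class = "ground_problem")
}

rand_gp <- function() {
  n <- sample(2:8, 1L)
  roles <- c("ARG0", "ARG1", "ARGM-LOC", "ARGX")[seq_len(sample(2:4, 1L))]
  st <- sample(0:8, n, replace = TRUE)
  en <- pmin(10L, st + sample(1:4, n, replace = TRUE))
  sc <- matrix(round(stats::rnorm(n * length(roles)), 2), n, length(roles),
               dimnames = list(NULL, roles))
  make_gp(sc, st, en)
}

# evaluation arguments of one tree/assignment pair as a data frame
args_of <- function(trees, assignments) {
  do.call(rbind, lapply(seq_along(trees), function(s) {
    a <- assignments[[s]]
    if (!length(a)) return(NULL)
    ids <- as.integer(names(a))
    data.frame(sentence = s, start = trees[[s]]$start[ids],
               end = trees[[s]]$end[ids], role = unname(a),
               stringsAsFactors = FALSE)
  }))
}
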