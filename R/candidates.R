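# Argument-candidate identification: association-rule mining over gold
# argument "transactions" (ARCI), word-list matching (WCI), regular-expression
# marker patterns (PCI), and a predicate-to-argument parse-path database
# (PTCI).  Nodes proposed by none of the enabled identifiers are discarded
# from the candidate pool.

#' Word lists for the word-based candidate identifier
#'
#' Discourse, modal and negation expressions matched (case-insensitively)
#' against a node's full span.  Parenthesised particles in the phrasal modals
#' are stored as full variants ("going to", "have to", "use to", "used to").
#'
#' @return a named list of character vectors (`ARGM-DIS`, `ARGM-MOD`,
#'   `ARGM-NEG`).
#' @export
wci_word_lists <- function() list(
  "ARGM-DIS" = c("additionally", "also", "altogether", "as well as",
    "but also", "by contrast", "conversely", "even", "finally", "further",
    "furthermore", "hence", "however", "importantly", "in addition",
    "in conclusion", "in contrast", "in fact", "in parallel", "in part",
    "in particular", "in sum", "in summary", "in this regard", "in turn",
    "indeed", "instead", "interestingly", "likewise", "moreover",
    "nevertheless", "no longer", "nonetheless", "not only", "on the contrary",
    "on the other hand", "probably", "rather", "still", "surprisingly",
    "then", "thereby", "therefore", "thus", "whereas"),
  "ARGM-MOD" = c("can", "could", "may", "might", "shall", "should", "would",
    "will", "going to", "going", "have to", "use to", "used to"),
  "ARGM-NEG" = c("not", "n't", "never", "no longer"))

#' Marker patterns for the pattern-based candidate identifier
#'
#' Canonical (cleaned) regular expressions for extent and temporal markers,
#' applied case-insensitively to a node's span text.
#'
#' @return a named character vector with entries `extent` and `temporal`.
#' @export
pci_patterns <- function() c(
  extent = "\\b(\\d+%|fold|extent|(greater|less) than \\d+)\\b",
  temporal = "\\b(year|month|week|day|hour|minute|min|second|sec|(\\d+|one|several)[-\\s]?(wk|hr|h))s?\\b")

# ---- transactions and rule mining (ARCI) ------------------------------------

# item set describing one node with respect to the predicate
node_items <- function(t, i, items = c("FW", "LW", "CT", "PATH", "verb_predicate")) {
  toks <- t$tokens[(t$start[i] + 1L):t$end[i]]
  vals <- c(
    FW = paste0("FW(", word_stem(toks[1]), ")"),
    LW = paste0("LW(", word_stem(toks[length(toks)]), ")"),
    CT = paste0("CT(", t$label[i], ")"),
    PATH = paste0("PATH(", syntactic_path(t, i, t$pred), ")"),
    verb_predicate = paste0("verb_predicate(", t$pred_lemma, ")"),
    FW_POS = paste0("FW_POS(", terminal_at(t, t$start[i]), ")"),
    LW_POS = paste0("LW_POS(", terminal_at(t, t$end[i] - 1L), ")"),
    PRED_POS = paste0("PRED_POS(", t$label[t$pred], ")"),
    VOICE = paste0("VOICE(", voice_of(t), ")"),
    POSITION = paste0("POSITION(", node_position(t, i), ")"))
  unname(vals[items])
}

# POS label of the terminal covering token position p (0-based)
terminal_at <- function(t, p) {
  i <- which(is_terminal(t) & t$start == p)
  if (length(i)) t$label[i[1]] else "NONE"
}

node_position <- function(t, i) {
  if (is.na(t$pred)) return("NONE")
  pt <- t$start[t$pred]
  if (t$end[i] <= pt) "before" else if (t$start[i] > pt) "after" else "overlap"
}

#' Extract gold-argument transactions from a corpus
#'
#' Every gold argument node of every tree becomes one transaction: its item
#' set over the requested predicates plus a `ROLE(...)` item.  Trees without a
#' marked verb predicate are skipped with a warning.
#'
#' @param corpus a list of `srl_tree` with gold roles.
#' @param items which item predicates to emit; defaults to the first/last-word
#'   stems, constituent type, syntactic path and verb-predicate lemma.  The
#'   extended pool adds `FW_POS`, `LW_POS`, `PRED_POS`, `VOICE`, `POSITION`.
#' @return a list of character vectors (one per gold argument node).
#' @export
extract_transactions <- function(corpus,
                                 items = c("FW", "LW", "CT", "PATH", "verb_predicate")) {
  if (inherits(corpus, "srl_tree")) corpus <- list(corpus)
  out <- list()
  for (t in corpus) {
    if (is.na(t$pred)) { warning("tree without a predicate node skipped"); next }
    for (i in gold_nodes(t))
      out[[length(out) + 1L]] <- c(node_items(t, i, items),
                                   paste0("ROLE(", t$role[i], ")"))
  }
  out
}

#' Rule confidence from supports
#'
#' `conf(X => Y) = supp(X and Y) / supp(X)`.
#'
#' @param joint_support support of the antecedent together with the role item.
#' @param antecedent_support support of the antecedent alone.
#' @return the confidence fraction.
#' @examples
#' rule_confidence(0.021, 0.022)  # ~0.9545, i.e. 95%
#' @export
rule_confidence <- function(joint_support, antecedent_support) {
  if (antecedent_support <= 0) stop("antecedent support must be positive")
  if (joint_support < 0 || joint_support > antecedent_support)
    stop("joint support must lie in [0, antecedent support]")
  joint_support / antecedent_support
}

#' Mine role association rules with the apriori algorithm
#'
#' Level-wise frequent-itemset enumeration over gold-argument transactions,
#' emitting rules whose sole consequent is a `ROLE(...)` item.  Support and
#' confidence are exact rational counts over the input transactions.
#'
#' @param transactions list of item-character-vectors from
#'   [extract_transactions()].
#' @param min_support minimum joint support in `(0, 1]`.
#' @param min_confidence minimum confidence in `(0, 1]`.
#' @param max_antecedent maximum antecedent size.
#' @return a data frame with columns `antecedent` (items joined by `" & "`),
#'   `role`, `support`, `confidence`, `count`, sorted by decreasing
#'   confidence then support.
#' @export
mine_rules <- function(transactions, min_support = 0.001, min_confidence = 0.90,
                       max_antecedent = 4L) {
  if (min_support <= 0 || min_support > 1) stop("min_support must be in (0, 1]")
  if (min_confidence <= 0 || min_confidence > 1) stop("min_confidence must be in (0, 1]")
  empty <- data.frame(antecedent = character(0), role = character(0),
                      support = numeric(0), confidence = numeric(0),
                      count = integer(0), stringsAsFactors = FALSE)
  nT <- length(transactions)
  if (!nT) return(empty)

  univ <- sort(unique(unlist(transactions)))
  # incidence matrix: items x transactions
  inc <- vapply(transactions, function(tr) univ %in% tr, logical(length(univ)))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = length(univ))
  rownames(inc) <- univ
  is_role <- startsWith(univ, "ROLE(")
  minc <- ceiling(min_support * nT - 1e-9)

  # level-wise search; an itemset is a sorted integer vector of row indices
  # containing at most one role item
  sup_count <- function(set) sum(colSums(inc[set, , drop = FALSE]) == length(set))
  freq <- list()          # all frequent itemsets, by size
  l1 <- which(rowSums(inc) >= max(minc, 1L))
  cur <- lapply(l1, function(i) i)
  counts <- list()
  level <- 1L
  max_size <- max_antecedent + 1L           # antecedent plus one role item
  while (length(cur) && level <= max_size) {
    cnt <- vapply(cur, sup_count, numeric(1))
    keep <- cnt >= max(minc, 1L)
    cur <- cur[keep]; cnt <- cnt[keep]
    freq[[level]] <- cur
    counts[[level]] <- cnt
    if (!length(cur) || level == max_size) break
    # candidate generation: join sets sharing all but the last element
    keys <- vapply(cur, function(s) paste(s[-length(s)], collapse = ","), character(1))
    lasts <- vapply(cur, function(s) s[length(s)], integer(1))
    nxt <- list()
    for (grp in split(seq_along(cur), keys)) {
      if (length(grp) < 2L) next
      ls <- sort(lasts[grp])
      for (a in seq_len(length(ls) - 1L)) for (b in (a + 1L):length(ls)) {
        cand <- c(cur[[grp[1]]][-length(cur[[grp[1]]])], ls[a], ls[b])
        if (sum(is_role[cand]) > 1L) next
        nxt[[length(nxt) + 1L]] <- cand
      }
    }
    cur <- unique(nxt)
    level <- level + 1L
  }

  # emit rules: frequent itemset with exactly one role item
  rows <- list()
  all_sets <- unlist(freq, recursive = FALSE)
  all_cnts <- unlist(counts)
  if (length(all_sets)) {
    set_key <- vapply(all_sets, paste, character(1), collapse = ",")
    cnt_of <- stats::setNames(all_cnts, set_key)
    for (k in seq_along(all_sets)) {
      set <- all_sets[[k]]
      ri <- which(is_role[set])
      if (length(ri) != 1L || length(set) < 2L) next
      ante <- set[-ri]
      akey <- paste(ante, collapse = ",")
      acnt <- if (akey %in% names(cnt_of)) cnt_of[[akey]] else sup_count(ante)
      conf <- all_cnts[k] / acnt
      if (conf + 1e-12 < min_confidence) next
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = paste(univ[ante], collapse = " & "),
        role = sub("^ROLE\\((.*)\\)$", "\\1", univ[set[ri]]),
        support = all_cnts[k] / nT, confidence = conf,
        count = as.integer(all_cnts[k]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$confidence, -out$support, out$antecedent, out$role), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Apply mined association rules to a tree's nodes
#'
#' A node matches a rule when every antecedent item holds for it; it then
#' gains the rule's role as a candidate.
#'
#' @param t an `srl_tree` with a predicate.
#' @param rules data frame from [mine_rules()].
#' @param items the item pool used at mining time.
#' @param nodes node indices to consider (default: all).
#' @return named list mapping node index to a character vector of roles.
#' @export
arci_identify <- function(t, rules,
                          items = c("FW", "LW", "CT", "PATH", "verb_predicate"),
                          nodes = seq_len(n_nodes(t))) {
  out <- list()
  if (!nrow(rules)) return(out)
  antes <- strsplit(rules$antecedent, " & ", fixed = TRUE)
  for (i in nodes) {
    its <- node_items(t, i, items)
    hit <- vapply(antes, function(a) all(a %in% its), logical(1))
    if (any(hit)) out[[as.character(i)]] <- sort(unique(rules$role[hit]))
  }
  out
}

# ---- word-based identifier (WCI) --------------------------------------------

#' Word-based candidate identifier
#'
#' Proposes `ARGM-DIS` for nodes whose full span matches a discourse
#' expression, and `ARGM-MOD` / `ARGM-NEG` for nodes whose span ends at the
#' token immediately preceding the verb predicate and matches the respective
#' list.  Matching is case-insensitive on the space-joined span.
#'
#' @param t an `srl_tree` with a predicate.
#' @param word_lists see [wci_word_lists()].
#' @param nodes node indices to consider.
#' @return named list mapping node index to candidate roles.
#' @export
wci_identify <- function(t, word_lists = wci_word_lists(),
                         nodes = seq_len(n_nodes(t))) {
  out <- list()
  dis <- tolower(word_lists[["ARGM-DIS"]])
  mod <- tolower(word_lists[["ARGM-MOD"]])
  neg <- tolower(word_lists[["ARGM-NEG"]])
  pt <- if (!is.na(t$pred)) t$start[t$pred] else NA_integer_
  for (i in nodes) {
    sp <- tolower(span_text(t, i))
    roles <- character(0)
    if (sp %in% dis) roles <- c(roles, "ARGM-DIS")
    if (!is.na(pt) && t$end[i] == pt) {
      if (sp %in% mod) roles <- c(roles, "ARGM-MOD")
      if (sp %in% neg) roles <- c(roles, "ARGM-NEG")
    }
    if (length(roles)) out[[as.character(i)]] <- roles
  }
  out
}

# ---- pattern-based identifier (PCI) -----------------------------------------

# siblings of every node on the path from the predicate terminal up to (and
# including the children of) its minimal clause ancestor
pci_scope <- function(t) {
  if (is.na(t$pred)) return(integer(0))
  chain <- c(t$pred, ancestors_of(t, t$pred))
  stopcl <- which(t$label[chain] %in% c("S", "SBAR", "SINV", "SQ"))
  top <- if (length(stopcl)) chain[stopcl[1]] else chain[length(chain)]
  sibs <- integer(0)
  for (nd in chain) {
    if (nd == top) break
    p <- t$parent[nd]
    sibs <- c(sibs, setdiff(t$children[[p]], nd))
  }
  unique(sibs)
}

#' Pattern-based candidate identifier
#'
#' Searches the sibling subtrees of the verb predicate (siblings of each node
#' on the predicate-to-clause path) for spans matching the extent pattern
#' (`ARGM-EXT`) or the temporal pattern (`ARGM-TMP`); additionally, any node
#' whose span starts at the first token of the sentence and matches the
#' temporal pattern is an `ARGM-TMP` candidate.
#'
#' @param t an `srl_tree` with a predicate.
#' @param patterns named patterns, see [pci_patterns()].
#' @param nodes node indices to consider.
#' @return named list mapping node index to candidate roles.
#' @export
pci_identify <- function(t, patterns = pci_patterns(),
                         nodes = seq_len(n_nodes(t))) {
  for (p in patterns)
    if (inherits(suppressWarnings(
          tryCatch(grepl(p, "x", perl = TRUE), error = identity)), "error"))
      stop("malformed candidate pattern: ", p)
  scope <- unique(unlist(lapply(pci_scope(t), function(s) subtree_nodes(t, s))))
  out <- list()
  add <- function(i, role) {
    k <- as.character(i)
    out[[k]] <<- sort(unique(c(out[[k]], role)))
  }
  for (i in intersect(nodes, scope)) {
    sp <- span_text(t, i)
    if (grepl(patterns[["extent"]], sp, ignore.case = TRUE, perl = TRUE))
      add(i, "ARGM-EXT")
    if (grepl(patterns[["temporal"]], sp, ignore.case = TRUE, perl = TRUE))
      add(i, "ARGM-TMP")
  }
  for (i in nodes[t$start[nodes] == 0L]) {
    sp <- span_text(t, i)
    if (grepl(patterns[["temporal"]], sp, ignore.case = TRUE, perl = TRUE))
      add(i, "ARGM-TMP")
  }
  out
}

# ---- parse-path identifier (PTCI) -------------------------------------------

#' Build the predicate-to-argument path database
#'
#' Records, for every gold argument node in the training corpus, the syntactic
#' path from the verb-predicate terminal to that node (in strict
#' predicate-first emission, so lookup does not depend on surface order)
#' together with the argument types observed at that path.
#'
#' @param corpus list of `srl_tree` with gold roles.
#' @return a named list mapping path string to a character vector of roles.
#' @export
build_path_db <- function(corpus) {
  if (inherits(corpus, "srl_tree")) corpus <- list(corpus)
  db <- list()
  for (t in corpus) {
    if (is.na(t$pred)) next
    for (i in gold_nodes(t)) {
      p <- syntactic_path(t, t$pred, i, order = "strict")
      db[[p]] <- sort(unique(c(db[[p]], t$role[i])))
    }
  }
  db
}

#' Parse-tree-based candidate identifier
#'
#' A node whose predicate-to-node path equals a path observed to reach an
#' argument in the training set gains all argument types recorded for that
#' path.
#'
#' @param t an `srl_tree` with a predicate.
#' @param path_db from [build_path_db()].
#' @param nodes node indices to consider.
#' @return named list mapping node index to candidate roles.
#' @export
ptci_identify <- function(t, path_db, nodes = seq_len(n_nodes(t))) {
  out <- list()
  if (!length(path_db) || is.na(t$pred)) return(out)
  for (i in nodes) {
    p <- syntactic_path(t, t$pred, i, order = "strict")
    if (!is.null(path_db[[p]])) out[[as.character(i)]] <- path_db[[p]]
  }
  out
}

# ---- combination ------------------------------------------------------------

#' Identify argument candidates for one tree
#'
#' Runs the enabled identifiers over the nodes surviving the tree-pruning
#' filter and unions their proposals.  Following the resource-saving design,
#' the parse-path identifier is consulted only for nodes not already proposed
#' by any other identifier.  Nodes with no proposals are discarded.
#'
#' @param t an `srl_tree` with a predicate.
#' @param surviving node indices from [apply_tpf()].
#' @param resources a list with elements `rules` (mined rules or `NULL`),
#'   `word_lists`, `patterns`, `path_db` (or `NULL`), `items`.
#' @param identifiers subset of `c("ARCI", "WCI", "PCI", "PTCI")`.
#' @return a data frame (`node`, `role`, `provenance`) — the candidate set.
#' @export
identify_candidates <- function(t, surviving = apply_tpf(t),
                                resources = list(),
                                identifiers = c("ARCI", "WCI", "PCI", "PTCI")) {
  props <- list()
  grab <- function(lst, prov) {
    for (k in names(lst))
      props[[length(props) + 1L]] <<- data.frame(
        node = as.integer(k), role = lst[[k]], provenance = prov,
        stringsAsFactors = FALSE)
  }
  if ("ARCI" %in% identifiers && !is.null(resources$rules))
    grab(arci_identify(t, resources$rules,
                       items = resources$items %||% c("FW", "LW", "CT", "PATH", "verb_predicate"),
                       nodes = surviving), "ARCI")
  if ("WCI" %in% identifiers)
    grab(wci_identify(t, resources$word_lists %||% wci_word_lists(),
                      nodes = surviving), "WCI")
  if ("PCI" %in% identifiers)
    grab(pci_identify(t, resources$patterns %||% pci_patterns(),
                      nodes = surviving), "PCI")
  claimed <- if (length(props)) unique(do.call(rbind, props)$node) else integer(0)
  if ("PTCI" %in% identifiers && !is.null(resources$path_db))
    grab(ptci_identify(t, resources$path_db,
                       nodes = setdiff(surviving, claimed)), "PTCI")
  if (!length(props))
    return(data.frame(node = integer(0), role = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, props))
  out <- out[order(out$node, out$role, out$provenance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
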