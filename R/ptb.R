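#' Read bracketed parse trees with role annotations
#'
#' Parses one or more Penn-Treebank-style bracketed trees.  The bundled
#' annotation dialect attaches gold roles to node labels with a `-ROLE` suffix
#' (e.g. `NP-ARG0`, `PP-ARGM-LOC`) and marks the verb-predicate terminal with a
#' `-PRED` suffix (e.g. `VBD-PRED`).  Terminals are written `(POS word)`.
#'
#' @param text a character vector holding bracketed trees (concatenated with
#'   newlines), or the path of a file when `is_file = TRUE`.
#' @param is_file read `text` as a file path?
#' @param lemmatizer function mapping an inflected verb to its lemma; used to
#'   fill `pred_lemma`.
#' @return a list of [new_srl_tree()] objects.
#' @examples
#' tr <- parse_ptb("(S (NP-ARG0 (NN T3)) (VP (VBD-PRED induced)))")[[1]]
#' tr$role[tr$label == "NP"]
#' @export
parse_ptb <- function(text, is_file = FALSE, lemmatizer = lemmatize_verb) {
  if (is_file) text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  text <- paste(text, collapse = "\n")
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  if (m[1] == -1L) return(list())
  toks <- regmatches(text, list(m))[[1]]
  pos <- as.integer(m)

  trees <- list()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    if (toks[i] != "(")
      stop("parse error at character ", pos[i], ": expected '(' but found '", toks[i], "'")
    acc <- new.env(parent = emptyenv())
    acc$label <- character(0); acc$parent <- integer(0); acc$word <- character(0)
    acc$start <- integer(0); acc$end <- integer(0); acc$role <- character(0)
    acc$pred <- integer(0); acc$tok <- character(0)
    i <- parse_node(toks, pos, i, NA_integer_, acc)
    if (length(acc$pred) > 1L)
      stop("tree marks ", length(acc$pred), " predicate terminals; the dialect allows one")
    pred <- if (length(acc$pred)) acc$pred else NA_integer_
    trees[[length(trees) + 1L]] <- new_srl_tree(
      label = acc$label, parent = acc$parent, word = acc$word,
      start = acc$start, end = acc$end, role = acc$role, tokens = acc$tok,
      pred = pred,
      pred_lemma = if (!is.na(pred)) lemmatizer(acc$word[pred]) else NA_character_)
  }
  trees
}

# recursive-descent helper; returns the token index one past this node
parse_node <- function(toks, pos, i, parent, acc) {
  stopifnot(toks[i] == "(")
  i <- i + 1L
  if (i > length(toks) || toks[i] %in% c("(", ")"))
    stop("parse error at character ", pos[min(i, length(toks))], ": missing node label")
  lab <- toks[i]
  id <- length(acc$label) + 1L
  parsed <- split_label(lab, pos[i])
  acc$label[id] <- parsed$label
  acc$role[id] <- parsed$role
  acc$parent[id] <- parent
  acc$word[id] <- NA_character_
  if (parsed$pred) acc$pred <- c(acc$pred, id)
  i <- i + 1L
  if (i > length(toks)) stop("parse error: unbalanced brackets at end of input")
  if (toks[i] == "(") {                      # internal node
    while (i <= length(toks) && toks[i] == "(")
      i <- parse_node(toks, pos, i, id, acc)
    if (i > length(toks) || toks[i] != ")")
      stop("parse error at character ",
           if (i <= length(toks)) pos[i] else nchar(paste(toks, collapse = "")),
           ": expected ')'")
    kids <- which(acc$parent == id)
    acc$start[id] <- min(acc$start[kids])
    acc$end[id] <- max(acc$end[kids])
  } else {                                   # terminal: (POS word)
    if (toks[i] == ")")
      stop("parse error at character ", pos[i], ": node '", lab, "' has no word or children")
    acc$word[id] <- toks[i]
    acc$start[id] <- length(acc$tok)
    acc$end[id] <- length(acc$tok) + 1L
    acc$tok <- c(acc$tok, toks[i])
    i <- i + 1L
    if (i > length(toks) || toks[i] != ")")
      stop("parse error at character ", pos[min(i, length(toks))],
           ": terminal '", lab, "' must hold exactly one token")
  }
  i + 1L
}

# split "NP-ARG0" / "VBD-PRED" into label, role, predicate flag
split_label <- function(lab, at = NA) {
  pred <- FALSE
  if (grepl("-PRED$", lab)) { pred <- TRUE; lab <- sub("-PRED$", "", lab) }
  role <- NA_character_
  m <- regmatches(lab, regexpr("-(C-|R-)?ARG.*$", lab))
  if (length(m) && nzchar(m)) {
    cand <- sub("^-", "", m)
    if (!is_valid_role(cand))
      stop("unknown role suffix '", cand, "'",
           if (!is.na(at)) paste0(" at character ", at) else "")
    role <- cand
    lab <- substr(lab, 1L, nchar(lab) - nchar(m))
  }
  if (!nzchar(lab)) stop("empty node label", if (!is.na(at)) paste0(" at character ", at))
  list(label = lab, role = role, pred = pred)
}

#' Write trees back to bracketed text
#'
#' Inverse of [parse_ptb()]: role suffixes and the `-PRED` marker are restored,
#' so `parse_ptb(write_ptb(trees))` round-trips.
#'
#' @param trees an `srl_tree` or list of them.
#' @param file optional path; when given, the text is written there.
#' @return the bracketed text, invisibly when `file` is given.
#' @export
write_ptb <- function(trees, file = NULL) {
  if (inherits(trees, "srl_tree")) trees <- list(trees)
  fmt1 <- function(t, i) {
    lab <- t$label[i]
    if (!is.na(t$role[i])) lab <- paste0(lab, "-", t$role[i])
    if (!is.na(t$pred) && i == t$pred) lab <- paste0(lab, "-PRED")
    if (is_terminal(t, i))
      paste0("(", lab, " ", t$word[i], ")")
    else
      paste0("(", lab, " ", paste(vapply(t$children[[i]], function(k) fmt1(t, k),
                                         character(1)), collapse = " "), ")")
  }
  out <- vapply(trees, function(t) fmt1(t, tree_root(t)), character(1))
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}
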