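# Local feature extraction per (node, predicate): the basis of the local
# formulae.  Every feature is emitted as a "name=value" string; absent
# structure yields the sentinel value "NONE".

#' Head-percolation table (Collins-style)
#'
#' Per constituent label: a scan direction and a priority list of child
#' labels.  The table is total via a fallback (leftmost child for
#' left-scanning labels, rightmost otherwise); `NP` uses the customary
#' dedicated rule.
#'
#' @return a named list of `list(dir, priority)`.
#' @export
collins_head_table <- function() list(
  ADJP  = list("left",  c("NNS", "QP", "NN", "$", "ADVP", "JJ", "VBN", "VBG",
                          "ADJP", "JJR", "NP", "JJS", "DT", "FW", "RBR", "RBS",
                          "SBAR", "RB")),
  ADVP  = list("right", c("RB", "RBR", "RBS", "FW", "ADVP", "TO", "CD", "JJR",
                          "JJ", "IN", "NP", "JJS", "NN")),
  CONJP = list("right", c("CC", "RB", "IN")),
  FRAG  = list("right", character(0)),
  INTJ  = list("left",  character(0)),
  LST   = list("right", c("LS", ":")),
  NAC   = list("left",  c("NN", "NNS", "NNP", "NNPS", "NP", "NAC", "EX", "$",
                          "CD", "QP", "PRP", "VBG", "JJ", "JJS", "JJR", "ADJP",
                          "FW")),
  PP    = list("right", c("IN", "TO", "VBG", "VBN", "RP", "FW")),
  PRN   = list("left",  character(0)),
  PRT   = list("right", "RP"),
  QP    = list("left",  c("$", "IN", "NNS", "NN", "JJ", "RB", "DT", "CD", "QP",
                          "JJR", "JJS")),
  RRC   = list("right", c("VP", "NP", "ADVP", "ADJP", "PP")),
  S     = list("left",  c("TO", "IN", "VP", "S", "SBAR", "ADJP", "UCP", "NP")),
  SBAR  = list("left",  c("WHNP", "WHPP", "WHADVP", "WHADJP", "IN", "DT", "S",
                          "SQ", "SINV", "SBAR", "FRAG")),
  SBARQ = list("left",  c("SQ", "S", "SINV", "SBARQ", "FRAG")),
  SINV  = list("left",  c("VBZ", "VBD", "VBP", "VB", "MD", "VP", "S", "SINV",
                          "ADJP", "NP")),
  SQ    = list("left",  c("VBZ", "VBD", "VBP", "VB", "MD", "VP", "SQ")),
  UCP   = list("right", character(0)),
  VP    = list("left",  c("TO", "VBD", "VBN", "MD", "VBZ", "VB", "VBG", "VBP",
                          "VP", "ADJP", "NN", "NNS", "NP")),
  WHADJP = list("left",  c("CC", "WRB", "JJ", "ADJP")),
  WHADVP = list("right", c("CC", "WRB")),
  WHNP  = list("left",  c("WDT", "WP", "WP$", "WHADJP", "WHPP", "WHNP")),
  WHPP  = list("right", c("IN", "TO", "FW")))

.np_head_priorities <- list(
  c("NN", "NNP", "NNPS", "NNS", "NX", "POS", "JJR"),
  "NP", c("$", "ADJP", "PRN"), "CD", c("JJ", "JJS", "RB", "QP"))

#' Head word of a node by head percolation
#'
#' Terminals are their own head; internal nodes select a head child from the
#' percolation table and recurse.
#'
#' @param t an `srl_tree`.
#' @param i node index.
#' @param table head table, see [collins_head_table()].
#' @return `list(word, pos, terminal)` — the head token, its POS tag and the
#'   head terminal's node index.
#' @examples
#' tr <- parse_ptb("(NP (JJ erythroid) (NN differentiation))")[[1]]
#' collins_head(tr, tree_root(tr))$word
#' @export
collins_head <- function(t, i, table = collins_head_table()) {
  while (!is_terminal(t, i)) i <- head_child(t, i, table)
  list(word = t$word[i], pos = t$label[i], terminal = i)
}

head_child <- function(t, i, table) {
  kids <- t$children[[i]]
  labs <- t$label[kids]
  lab <- t$label[i]
  if (lab == "NP" || lab == "NX") {
    if (labs[length(labs)] == "POS") return(kids[length(kids)])
    for (g in seq_along(.np_head_priorities)) {
      pri <- .np_head_priorities[[g]]
      scan <- if (g == 2L) kids else rev(kids)
      hit <- scan[t$label[scan] %in% pri]
      if (length(hit)) return(hit[1])
    }
    return(kids[length(kids)])
  }
  rule <- table[[lab]]
  if (is.null(rule)) return(kids[1])
  scan <- if (rule[[1]] == "left") kids else rev(kids)
  for (p in rule[[2]]) {
    hit <- scan[t$label[scan] == p]
    if (length(hit)) return(hit[1])
  }
  scan[1]
}

#' Voice of the verb predicate
#'
#' Passive when the predicate's POS tag is `VBN` and either no `VP` ancestor
#' exists (a reduced form outside a verb phrase) or a form of *to be* / *to
#' get* precedes the predicate within its verb-phrase chunk (the yield of the
#' outermost `VP` ancestor); otherwise active.
#'
#' @param t an `srl_tree`.
#' @param pred predicate terminal index (defaults to the tree's).
#' @return `"active"` or `"passive"`.
#' @export
voice_of <- function(t, pred = t$pred) {
  if (is.na(pred) || t$label[pred] != "VBN") return("active")
  anc <- ancestors_of(t, pred)
  vps <- anc[t$label[anc] == "VP"]
  if (!length(vps)) return("passive")
  top <- vps[length(vps)]
  before <- t$tokens[(t$start[top] + 1L):t$end[top]]
  before <- tolower(before[seq_len(t$start[pred] - t$start[top])])
  aux <- c("be", "is", "am", "are", "was", "were", "been", "being", "'s", "'re",
           "'m", "get", "gets", "got", "gotten", "getting")
  if (length(before) && any(before %in% aux)) "passive" else "active"
}

#' Corpus-level feature context
#'
#' Collects the statistics some features need: verb-predicate lemma
#' frequencies (bucketed `1`, `2-5`, `6-20`, `>20`) and the number of verb
#' predicates per sentence (one per tree here).
#'
#' @param corpus list of `srl_tree`.
#' @return a `feature_context` list.
#' @export
feature_context <- function(corpus) {
  lem <- vapply(corpus, function(t) t$pred_lemma %||% NA_character_, character(1))
  tab <- table(lem[!is.na(lem)])
  structure(list(pred_freq = tab), class = "feature_context")
}

freq_bucket <- function(n) {
  if (is.na(n) || n < 1) "NONE"
  else if (n == 1) "1" else if (n <= 5) "2-5" else if (n <= 20) "6-20" else ">20"
}

dist_bucket <- function(n) {
  if (n <= 2) as.character(n) else if (n <= 4) "3-4" else if (n <= 8) "5-8" else ">8"
}

#' Extract local features for one (node, predicate) pair
#'
#' Emits the full feature inventory as `name=value` strings: basic features
#' (predicate lemma, syntactic path, constituent type, position, voice, head
#' word/POS, sub-categorization, first/last word and POS, level), verb
#' predicate features (POS, class, frequency bucket, context POS, number of
#' predicates), full-parsing features (parent and sibling paths, types,
#' positions, heads; head of a PP parent), combination features, and the
#' remainder (syntactic frame, head-word suffixes of lengths 2--4, phrase
#' length, context words and POS).  Extraction is deterministic and pure.
#'
#' @param t an `srl_tree` with a predicate.
#' @param i node index.
#' @param ctx optional [feature_context()].
#' @param head_table head-percolation table.
#' @return a character vector of `name=value` features.
#' @export
extract_features <- function(t, i, ctx = NULL, head_table = collins_head_table()) {
  pred <- t$pred
  lem <- t$pred_lemma
  hd <- collins_head(t, i, head_table)
  hw <- tolower(hd$word)
  path <- syntactic_path(t, i, pred)
  pos <- node_position(t, i)
  vc <- voice_of(t)
  toks <- t$tokens[(t$start[i] + 1L):t$end[i]]
  fw <- word_stem(toks[1]); lw <- word_stem(toks[length(toks)])
  lvl <- node_depth(t, i)
  pp <- t$parent[pred]
  subcat <- if (!is.na(pp))
    paste0(t$label[pp], "->", paste(t$label[t$children[[pp]]], collapse = "-"))
  else "NONE"

  rel <- function(j, tag) {
    if (is.na(j) || !length(j)) return(c(
      paste0(tag, "_path=NONE"), paste0(tag, "_ct=NONE"),
      paste0(tag, "_pos=NONE"), paste0(tag, "_hw=NONE"),
      paste0(tag, "_hwpos=NONE")))
    h <- collins_head(t, j, head_table)
    c(paste0(tag, "_path=", syntactic_path(t, j, pred)),
      paste0(tag, "_ct=", t$label[j]),
      paste0(tag, "_pos=", node_position(t, j)),
      paste0(tag, "_hw=", tolower(h$word)),
      paste0(tag, "_hwpos=", h$pos))
  }
  par <- t$parent[i]
  sibs <- if (!is.na(par)) t$children[[par]] else integer(0)
  k <- match(i, sibs)
  ls <- if (!is.na(par) && k > 1L) sibs[k - 1L] else NA_integer_
  rs <- if (!is.na(par) && k < length(sibs)) sibs[k + 1L] else NA_integer_

  ctx_pos <- function(p) terminal_at(t, p)
  ptok <- t$start[pred]
  nfeat <- c(
    # basic
    paste0("vp=", lem),
    paste0("path=", path),
    paste0("ct=", t$label[i]),
    paste0("pos=", pos),
    paste0("voice=", vc),
    paste0("hw=", hw),
    paste0("hwpos=", hd$pos),
    paste0("subcat=", subcat),
    paste0("fw=", fw), paste0("fwpos=", terminal_at(t, t$start[i])),
    paste0("lw=", lw), paste0("lwpos=", terminal_at(t, t$end[i] - 1L)),
    paste0("lvl=", lvl),
    # verb-predicate
    paste0("vpos=", t$label[pred]),
    paste0("vclass=", lem),
    paste0("vfreq=", freq_bucket(
      if (!is.null(ctx)) ctx$pred_freq[lem] else NA_integer_)),
    paste0("vctx=", if (ptok > 0L) ctx_pos(ptok - 1L) else "BOS", "_",
           if (ptok < length(t$tokens) - 1L) ctx_pos(ptok + 1L) else "EOS"),
    paste0("nvp=", 1L),
    # full parsing
    rel(par, "par"), rel(ls, "ls"), rel(rs, "rs"),
    paste0("pp_par_hw=", if (!is.na(par) && t$label[par] == "PP")
      tolower(collins_head(t, par, head_table)$word) else "NONE"),
    # combinations
    paste0("hw_vp=", hw, "|", lem),
    paste0("voice_pos=", vc, "|", pos),
    paste0("vp_dist=", lem, "|", dist_bucket(length(parse_path(path)$labels))),
    paste0("vp_ct=", lem, "|", t$label[i]),
    # others
    paste0("synframe=", syn_frame(t, i, pred)),
    paste0("hwsuf2=", substr_right(hw, 2L)),
    paste0("hwsuf3=", substr_right(hw, 3L)),
    paste0("hwsuf4=", substr_right(hw, 4L)),
    paste0("nw=", dist_bucket(length(toks))),
    paste0("cw_l=", if (t$start[i] > 0L) tolower(t$tokens[t$start[i]]) else "BOS"),
    paste0("cw_r=", if (t$end[i] < length(t$tokens)) tolower(t$tokens[t$end[i] + 1L]) else "EOS"),
    paste0("cp_l=", if (t$start[i] > 0L) ctx_pos(t$start[i] - 1L) else "BOS"),
    paste0("cp_r=", if (t$end[i] < length(t$tokens)) ctx_pos(t$end[i]) else "EOS"))
  nfeat
}

substr_right <- function(x, n) substr(x, max(1L, nchar(x) - n + 1L), nchar(x))

# sibling constituent labels around the predicate's VP, with the target
# node's position marked when it is one of them
syn_frame <- function(t, i, pred) {
  vp <- t$parent[pred]
  if (is.na(vp)) return("NONE")
  par <- t$parent[vp]
  around <- if (!is.na(par)) t$children[[par]] else vp
  labs <- t$label[around]
  labs[around == i] <- paste0("[", labs[around == i], "]")
  paste(labs, collapse = "_")
}
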