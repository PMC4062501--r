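# Seeded generator of annotated synthetic corpora shaped like a biomedical
# proposition bank, plus bundled fixture sentences for the worked examples.
#
# Generated sentences follow a clause template
#   [DIS]? [TMP]? NP-ARG0 [MOD|NEG]? (VP V NP-ARG1 [EXT]? [ARG2]? [LOC]?
#                                        [TMP]? [MNR]?)
# with a passive variant (ARG1 subject, optional by-PP ARG0).  Gold roles sit
# on phrasal (internal, multi-child-sibling) nodes so that by construction
# every gold argument survives the default tree-pruning filter, and gold
# assignments always satisfy the collective constraints.  Role-correlated
# vocabulary carries the configurable signal; distractor noun phrases with
# agent/patient-like vocabulary are planted to create the duplicate- and
# overlapping-argument ambiguities that collective decoding resolves.

#' Generator configuration
#'
#' @param n_sentences number of sentences to generate.
#' @param seed RNG seed; the same configuration generates a byte-identical
#'   corpus.
#' @param n_predicates number of verb-predicate lemmas used (drawn from
#'   [verb_lexicon()], max 30).
#' @param core_roles core argument inventory (default 11 labels).
#' @param adjunct_roles adjunct argument inventory (default 21 `ARGM-*`).
#' @param signal probability that a gold argument's vocabulary is drawn from
#'   its role-specific pool rather than the shared confounder pool.
#' @param distractor_prob probability of planting a non-argument noun phrase
#'   with agent-like vocabulary (duplicate-argument ambiguity).
#' @param overlap_prob probability of nesting a patient-like noun phrase
#'   inside the ARG1 constituent (overlapping-argument ambiguity).
#' @param passive_prob probability of the passive template.
#' @return a `gen_config` list.
#' @export
gen_config <- function(n_sentences = 100L, seed = 1L, n_predicates = 30L,
                       core_roles = c("ARG0", "ARG1", "ARG2", "ARG3", "ARG4",
                                      "ARG5", "ARGX", "R-ARG0", "R-ARG1",
                                      "C-ARG0", "C-ARG1"),
                       adjunct_roles = paste0("ARGM-", c(
                         "ADV", "CAU", "CND", "COM", "DIR", "DIS", "DSP",
                         "EXT", "GOL", "LOC", "LVB", "MNR", "MOD", "NEG",
                         "PNC", "PRD", "PRP", "REC", "RCL", "SLC", "TMP")),
                       signal = 0.9, distractor_prob = 0.3,
                       overlap_prob = 0.3, passive_prob = 0.25) {
  if (n_sentences < 1L) stop("n_sentences must be positive")
  if (n_predicates < 1L || !length(core_roles) || !length(adjunct_roles))
    stop("inventory sizes must be positive")
  structure(list(n_sentences = as.integer(n_sentences), seed = as.integer(seed),
                 n_predicates = min(as.integer(n_predicates), 30L),
                 core_roles = core_roles, adjunct_roles = adjunct_roles,
                 signal = signal, distractor_prob = distractor_prob,
                 overlap_prob = overlap_prob, passive_prob = passive_prob),
            class = "gen_config")
}

.gen_vocab <- list(
  agent = c("kinase", "receptor", "factor", "enzyme", "ligand", "activator",
            "regulator", "promoter", "antibody", "operon", "homolog",
            "effector", "complex", "subunit", "repressor"),
  patient = c("differentiation", "transcription", "expression", "apoptosis",
              "proliferation", "pathway", "response", "cascade", "gene",
              "cytokine", "interleukin", "phosphorylation", "activation",
              "migration", "adhesion"),
  arg2 = c("nucleus", "membrane", "cytoplasm", "chromatin", "ribosome",
           "genome", "vesicle", "promoter-region"),
  shared = c("molecule", "sample", "system", "region", "element", "domain",
             "site", "sequence", "structure", "target"),
  cell = c("cells", "lymphocytes", "monocytes", "fibroblasts", "neutrophils",
           "hepatocytes", "thymocytes", "macrophages"),
  adj = c("erythroid", "myeloid", "human", "murine", "nuclear", "viral",
          "cellular", "transcriptional", "mitogenic", "basal"),
  mnr = c("efficiently", "rapidly", "strongly", "specifically", "markedly",
          "transiently", "selectively", "dramatically"),
  dis = list(c("IN in", "NN addition"), c("IN in", "NN contrast"),
             c("IN in", "NN turn"), c("IN in", "NN fact"),
             c("IN by", "NN contrast"),
             c("IN on", "DT the", "JJ other", "NN hand")))

#' Generate a synthetic annotated corpus
#'
#' @param config a [gen_config()].
#' @return a list of `srl_tree` with gold roles and marked predicates.
#' @examples
#' corpus <- generate_corpus(gen_config(n_sentences = 5, seed = 7))
#' corpus[[1]]
#' @export
generate_corpus <- function(config = gen_config()) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  lemmas <- verb_lexicon()[seq_len(config$n_predicates)]
  text <- vapply(seq_len(config$n_sentences), function(k)
    gen_sentence(config, lemmas), character(1))
  parse_ptb(paste(text, collapse = "\n"))
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

# noun phrase "(NP (DT the) (JJ adj)* (NN mod)? (NN head))" with role-pool
# vocabulary; word-count variability keeps phrase length uninformative
gen_np <- function(config, pool, role = NULL, plural = FALSE) {
  voc <- if (stats::runif(1) < config$signal) .gen_vocab[[pool]]
         else .gen_vocab$shared
  head <- pick(voc)
  tag <- if (plural) "NNS" else "NN"
  nadj <- sample(0:2, 1L, prob = c(0.4, 0.4, 0.2))
  kids <- c("(DT the)",
            if (nadj) vapply(seq_len(nadj), function(i)
              paste0("(JJ ", pick(.gen_vocab$adj), ")"), character(1)),
            if (stats::runif(1) < 0.3)
              paste0("(NN ", pick(.gen_vocab$shared), ")"),
            paste0("(", tag, " ", head, ")"))
  lab <- if (is.null(role)) "NP" else paste0("NP-", role)
  paste0("(", lab, " ", paste(kids, collapse = " "), ")")
}

gen_sentence <- function(config, lemmas) {
  lemma <- pick(lemmas)
  passive <- stats::runif(1) < config$passive_prob
  pre <- character(0)

  if (stats::runif(1) < 0.25) {
    d <- pick(.gen_vocab$dis)
    pre <- c(pre, paste0("(ADVP-ARGM-DIS ",
                         paste0("(", d, ")", collapse = " "), ")"))
  }
  if (stats::runif(1) < 0.15)
    pre <- c(pre, paste0("(PP-ARGM-TMP (IN after) (NP (CD ",
                         sample(2:48, 1L), ") (NNS hours)))"))

  vp_mods <- character(0)
  if (stats::runif(1) < config$distractor_prob)
    vp_mods <- c(vp_mods, paste0("(PP (IN with) ", gen_np(config, "agent"), ")"))
  if (stats::runif(1) < 0.15)
    vp_mods <- c(vp_mods, paste0("(ADVP-ARGM-EXT (RB approximately) (RB ",
                                 sample(2:20, 1L), "-fold))"))
  if (stats::runif(1) < 0.2)
    vp_mods <- c(vp_mods, paste0("(PP-ARG2 (TO to) ", gen_np(config, "arg2"), ")"))
  if (stats::runif(1) < 0.35)
    vp_mods <- c(vp_mods, paste0("(PP-ARGM-LOC (IN in) (NP (DT these) (NNS ",
                                 pick(.gen_vocab$cell), ")))"))
  if (stats::runif(1) < 0.15)
    vp_mods <- c(vp_mods, "(PP-ARGM-TMP (IN for) (NP (JJ several) (NNS hours)))")
  if (stats::runif(1) < 0.2)
    vp_mods <- c(vp_mods, paste0("(ADVP-ARGM-MNR (RB ", pick(.gen_vocab$mnr), "))"))
  mods <- if (length(vp_mods)) paste(" ", paste(vp_mods, collapse = " ")) else ""

  # ARG1 object, optionally with a nested patient-like distractor
  arg1 <- if (stats::runif(1) < config$overlap_prob) {
    paste0("(NP-ARG1 ", gen_np(config, "patient"), " (PP (IN of) ",
           gen_np(config, "patient"), "))")
  } else gen_np(config, "patient", role = "ARG1")

  if (!passive) {
    # with probability overlap_prob the agent sits inside a wrapper noun
    # phrase ("the factor of the regulator"); the wrapper's local features
    # (path, head, first/last word, length) are distributed like a plain
    # gold subject's, so only joint decoding can avoid labeling both
    subj <- if (stats::runif(1) < config$overlap_prob)
      paste0("(NP ", gen_np(config, "agent", role = "ARG0"), " (PP (IN of) ",
             gen_np(config, "agent"), "))")
    else gen_np(config, "agent", role = "ARG0")
    aux <- if (stats::runif(1) < 0.1) "(ADVP-ARGM-NEG (RB no) (RB longer)) "
           else if (stats::runif(1) < 0.1) "(ADVP-ARGM-MOD (VBG going) (TO to)) "
           else ""
    vform <- if (nzchar(aux) && grepl("MOD", aux))
      paste0("(VB-PRED ", lemma, ")")
    else if (stats::runif(1) < 0.5)
      paste0("(VBD-PRED ", inflect_verb(lemma)[2], ")")
    else paste0("(VBZ-PRED ", inflect_verb(lemma)[1], ")")
    body <- paste0("(VP ", vform, " ", arg1, mods, ")")
    paste0("(S ", paste(c(pre, subj, aux), collapse = " "),
           if (length(pre) || nzchar(aux)) " ", body, ")")
  } else {
    subj <- if (stats::runif(1) < config$overlap_prob) {
      paste0("(NP-ARG1 ", gen_np(config, "patient"), " (PP (IN of) ",
             gen_np(config, "patient"), "))")
    } else gen_np(config, "patient", role = "ARG1")
    byp <- if (stats::runif(1) < 0.7)
      paste0(" (PP-ARG0 (IN by) ", gen_np(config, "agent"), ")") else ""
    body <- paste0("(VP (VBD was) (VP (VBN-PRED ", inflect_verb(lemma)[2],
                   ")", byp, mods, "))")
    paste0("(S ", paste(c(pre, subj), collapse = " "), " ", body, ")")
  }
}

#' Bundled fixture sentences
#'
#' Hand-reconstructed trees for the worked examples: the extent-marker
#' sentence, the two rule-mining sentences, and the four discussion sentences
#' exhibiting duplicate-argument, overlapping-argument, adverbial-clause and
#' candidate-pruning phenomena.  See the README in
#' `inst/extdata/fixtures/` for the reconstruction notes.
#'
#' @return a named list of `srl_tree`: `extent`, `mining_a`, `mining_b`,
#'   `duplicate`, `overlap`, `adverbial`, `pruning_error`.
#' @export
fixture_sentences <- function() {
  dir <- system.file("extdata", "fixtures", package = "srlkit", mustWork = TRUE)
  rd <- function(f) parse_ptb(file.path(dir, f), is_file = TRUE)
  disc <- rd("discussion.ptb")
  c(list(extent = rd("fig_extent.ptb")[[1]],
         mining_a = rd("fig_mining_a.ptb")[[1]],
         mining_b = rd("fig_mining_b.ptb")[[1]]),
    stats::setNames(disc, c("duplicate", "overlap", "adverbial",
                            "pruning_error")))
}

#' Expected transactions of the rule-mining fixtures
#'
#' The ten worked transactions, both as printed in the source material
#' (`path_printed`) and as realizable from a single coherent tree (`path`);
#' they differ in three rows, at documented typo positions.
#'
#' @return a data frame with columns `figure`, `ct`, `fw`, `lw`,
#'   `verb_predicate`, `role`, `path_printed`, `path`.
#' @export
expected_mining_transactions <- function() {
  f <- system.file("extdata", "fixtures", "fig_mining_transactions.tsv",
                   package = "srlkit", mustWork = TRUE)
  utils::read.table(f, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}
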