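# Transactions, apriori rule mining, and the four candidate identifiers.

norm_tx <- function(tx) sort(vapply(tx, function(x)
  paste(sort(tolower(x)), collapse = " | "), character(1)))

expected_tx <- function(fig) {
  d <- expected_mining_transactions()
  d <- d[d$figure == fig, ]
  lapply(seq_len(nrow(d)), function(k) c(
    paste0("FW(", d$fw[k], ")"), paste0("LW(", d$lw[k], ")"),
    paste0("CT(", d$ct[k], ")"), paste0("PATH(", d$path[k], ")"),
    paste0("verb_predicate(", d$verb_predicate[k], ")"),
    paste0("ROLE(", d$role[k], ")")))
}

test_that("the worked rule-mining fixtures yield the expected transactions", {
  fx <- fixture_sentences()
  ta <- extract_transactions(fx$mining_a)
  tb <- extract_transactions(fx$mining_b)
  expect_length(ta, 6L)
  expect_length(tb, 4L)
  expect_identical(norm_tx(ta), norm_tx(expected_tx("a")))
  expect_identical(norm_tx(tb), norm_tx(expected_tx("b")))
  expect_length(extract_transactions(list()), 0L)
  noPred <- parse_ptb("(S (NP-ARG0 (NN a)) (VP (VBD ran)))")[[1]]
  expect_warning(extract_transactions(list(noPred)), "predicate")
})

test_that("realizable paths differ from the printed text only at the three documented typo rows", {
  d <- expected_mining_transactions()
  mismatch <- d[d$path != d$path_printed, ]
  expect_identical(nrow(mismatch), 3L)
  expect_true(all(mismatch$figure == "b"))
  expect_setequal(mismatch$role, c("ARG1", "ARGM-NEG", "ARGM-LOC"))
  # figure (a) is reproduced fully verbatim
  expect_true(all(d$path[d$figure == "a"] == d$path_printed[d$figure == "a"]))
})

test_that("confidence is the joint-to-antecedent support quotient", {
  expect_equal(rule_confidence(0.021, 0.022), 0.021 / 0.022)
  expect_identical(round(100 * rule_confidence(0.021, 0.022)), 95)
  expect_identical(rule_confidence(0.4, 0.4), 1)
  expect_error(rule_confidence(0.1, 0), "positive")
  expect_error(rule_confidence(0.3, 0.2), "joint")
})

test_that("mined rules carry exact rational counts (21-of-22 case)", {
  tx <- c(rep(list(c("FW(in)", "LW(cell)", "ROLE(ARGM-LOC)")), 21),
          list(c("FW(in)", "LW(cell)", "ROLE(ARG1)")),
          rep(list(c("FW(the)", "LW(gene)", "ROLE(ARG0)")), 8))
  r <- mine_rules(tx, min_support = 0.01, min_confidence = 0.5)
  hit <- r[r$antecedent == "FW(in) & LW(cell)" & r$role == "ARGM-LOC", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$confidence, 21 / 22)
  expect_equal(hit$support, 21 / 30)
  expect_identical(hit$count, 21L)
})

test_that("maximal support on heterogeneous transactions mines nothing", {
  tx <- list(c("FW(a)", "ROLE(ARG0)"), c("FW(b)", "ROLE(ARG1)"))
  expect_identical(nrow(mine_rules(tx, min_support = 1.0, min_confidence = 0.5)), 0L)
  expect_error(mine_rules(tx, 0, 0.5), "min_support")
  expect_error(mine_rules(tx, 0.5, 1.5), "min_confidence")
})

test_that("apriori equals exhaustive enumeration on small transaction sets", {
  set.seed(31)
  items <- c("FW(in)", "FW(the)", "LW(cell)", "LW(gene)", "CT(NP)", "CT(PP)")
  roles <- c("ROLE(ARG0)", "ROLE(ARGM-LOC)")
  for (trial in 1:12) {
    n <- sample(3:12, 1)
    tx <- lapply(seq_len(n), function(i)
      c(sample(items, sample(2:4, 1)), sample(roles, 1)))
    ms <- sample(c(0.05, 0.2, 0.4), 1)
    mc <- sample(c(0.5, 0.8, 1.0), 1)
    got <- rule_keys(mine_rules(tx, ms, mc))
    want <- brute_rules(tx, ms, mc)
    expect_identical(got, want)
  }
})

test_that("word-list identification requires exact spans and adjacency", {
  t1 <- parse_ptb("(S (ADVP (RB however)) (NP (NN protein)) (VP (VBD-PRED bound)))")[[1]]
  w1 <- wci_identify(t1)
  advp <- as.character(which(t1$label == "ADVP"))
  expect_identical(w1[[advp]], "ARGM-DIS")
  expect_false(as.character(which(t1$label == "NP")) %in% names(w1))

  # "will" right before the predicate is modal; elsewhere it is nothing
  t2 <- parse_ptb("(S (NP (NN factor)) (VP (MD will) (VP (VB-PRED bind))))")[[1]]
  md <- as.character(which(t2$label == "MD"))
  expect_identical(wci_identify(t2)[[md]], "ARGM-MOD")
  t3 <- parse_ptb("(S (NP (MD will) (NN power)) (VP (VBD-PRED failed) (NP (NN test))))")[[1]]
  expect_null(wci_identify(t3)[[as.character(which(t3$label == "MD"))]])
})

test_that("every modal/negation candidate is strictly left-adjacent to the predicate", {
  corpus <- rand_corpus(80, seed = 37)
  for (t in corpus) {
    w <- wci_identify(t)
    for (k in names(w))
      if (any(w[[k]] %in% c("ARGM-MOD", "ARGM-NEG")))
        expect_identical(t$end[as.integer(k)], t$start[t$pred])
  }
})

test_that("pattern identification searches predicate siblings and sentence starts", {
  fx <- fixture_sentences()
  p <- pci_identify(fx$extent)
  extn <- which(!is.na(fx$extent$role) & fx$extent$role == "ARGM-EXT")
  expect_true("ARGM-EXT" %in% p[[as.character(extn)]])

  # temporal pattern forms
  pat <- pci_patterns()[["temporal"]]
  expect_true(grepl(pat, "24 h", ignore.case = TRUE, perl = TRUE))
  expect_true(grepl(pat, "48 hrs", ignore.case = TRUE, perl = TRUE))
  expect_true(grepl(pat, "several weeks", ignore.case = TRUE, perl = TRUE))
  expect_false(grepl(pat, "the cell", ignore.case = TRUE, perl = TRUE))
  expect_false(grepl(pci_patterns()[["extent"]], "the cell",
                     ignore.case = TRUE, perl = TRUE))

  # a sentence-initial temporal phrase is proposed even off the sibling path
  t1 <- parse_ptb("(S (PP (IN after) (NP (CD 24) (NNS hours))) (NP (NN factor)) (VP (VBD-PRED rose)))")[[1]]
  pp <- as.character(which(t1$label == "PP"))
  expect_true("ARGM-TMP" %in% pci_identify(t1)[[pp]])
  expect_error(pci_identify(t1, patterns = c(extent = "(", temporal = "x")),
               "malformed")
})

test_that("path-database lookup equals a linear scan over training paths", {
  train <- rand_corpus(40, seed = 41)
  test <- rand_corpus(25, seed = 43)
  db <- build_path_db(train)
  # oracle: flat table of (path, role) pairs
  flat <- do.call(rbind, lapply(train, function(t)
    do.call(rbind, lapply(gold_nodes(t), function(i)
      data.frame(path = syntactic_path(t, t$pred, i, order = "strict"),
                 role = t$role[i], stringsAsFactors = FALSE)))))
  for (t in test) {
    got <- ptci_identify(t, db)
    for (i in seq_along(t$label)) {
      p <- syntactic_path(t, t$pred, i, order = "strict")
      want <- sort(unique(flat$role[flat$path == p]))
      if (length(want)) expect_identical(got[[as.character(i)]], want)
      else expect_null(got[[as.character(i)]])
    }
  }
  expect_length(ptci_identify(test[[1]], list()), 0L)
})

test_that("the long adverbial clause is recovered through the path database", {
  fx <- fixture_sentences()
  adv <- fx$adverbial
  sbar <- which(adv$label == "SBAR" & !is.na(adv$role))
  # a database that saw ARGM-ADV and ARGM-TMP at this path proposes both
  p <- syntactic_path(adv, adv$pred, sbar, order = "strict")
  db <- stats::setNames(list(c("ARGM-ADV", "ARGM-TMP")), p)
  got <- ptci_identify(adv, db)
  expect_identical(got[[as.character(sbar)]], c("ARGM-ADV", "ARGM-TMP"))
  cand <- identify_candidates(adv, apply_tpf(adv), list(path_db = db),
                              identifiers = "PTCI")
  expect_setequal(cand$role[cand$node == sbar], c("ARGM-ADV", "ARGM-TMP"))
})

test_that("candidate combination honors provenance, filtering and monotonicity", {
  corpus <- rand_corpus(30, seed = 47)
  res <- list(rules = mine_rules(extract_transactions(corpus), 0.01, 0.8),
              path_db = build_path_db(corpus))
  t <- corpus[[1]]
  surv <- apply_tpf(t)
  expect_identical(nrow(identify_candidates(t, surv, res,
                                            identifiers = character(0))), 0L)
  full <- identify_candidates(t, surv, res)
  expect_true(all(full$node %in% surv))
  expect_true(all(full$provenance %in% c("ARCI", "WCI", "PCI", "PTCI")))
  # provenance-tagged proposals equal the per-identifier runs on its scope
  arci_only <- identify_candidates(t, surv, res, identifiers = "ARCI")
  reset <- function(d) { rownames(d) <- NULL; d }
  expect_identical(reset(full[full$provenance == "ARCI", c("node", "role")]),
                   reset(arci_only[, c("node", "role")]))
  # node-level monotonicity: adding identifiers never removes a node
  sets <- list("WCI", c("WCI", "PCI"), c("WCI", "PCI", "ARCI"),
               c("WCI", "PCI", "ARCI", "PTCI"))
  prev <- integer(0)
  for (s in sets) {
    cur <- unique(identify_candidates(t, surv, res, identifiers = s)$node)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("generated gold arguments are always covered by the identifiers", {
  train <- rand_corpus(60, seed = 53)
  test <- rand_corpus(30, seed = 59)
  res <- list(rules = mine_rules(extract_transactions(train), 0.001, 0.9),
              path_db = build_path_db(train))
  for (t in test) {
    cand <- identify_candidates(t, apply_tpf(t), res)
    expect_true(all(gold_nodes(t) %in% cand$node))
  }
})
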