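# Bracketed-tree reading/writing, spans, syntactic paths, props columns.

test_that("parsing attaches roles, predicates and token spans", {
  tr <- parse_ptb("(S (NP-ARG0 (NN T3)) (VP (VBD-PRED induced)))")[[1]]
  expect_s3_class(tr, "srl_tree")
  expect_identical(tr$tokens, c("T3", "induced"))
  np <- which(tr$label == "NP")
  expect_identical(tr$role[np], "ARG0")
  expect_identical(tr$word[tr$pred], "induced")
  expect_identical(tr$pred_lemma, "induce")
  expect_true(is.na(tr$role[tr$pred]))

  one <- parse_ptb("(NN dog)")[[1]]
  expect_identical(length(one$label), 1L)
  expect_identical(c(one$start, one$end), c(0L, 1L))
  expect_identical(one$word, "dog")
})

test_that("malformed input is rejected with located errors", {
  expect_error(parse_ptb("(S (NP (NN dog))"), "unbalanced|expected")
  expect_error(parse_ptb("(S (NP-ARGQ (NN dog)) (VP (VBD ran)))"),
               "unknown role suffix")
  expect_error(parse_ptb("(S (NP-ARG0 (NN a)) (VP (VBD-PRED x) (VBD-PRED y)))"),
               "predicate")
  err <- tryCatch(parse_ptb("(S (NP (NN dog)) ))"), error = conditionMessage)
  expect_match(err, "character [0-9]+")
})

test_that("internal spans tile their children on generated trees", {
  for (t in rand_corpus(30, seed = 42)) {
    term <- !is.na(t$word)
    expect_true(all(t$end[term] - t$start[term] == 1L))
    for (i in which(!term)) {
      k <- t$children[[i]]
      expect_identical(t$start[i], min(t$start[k]))
      expect_identical(t$end[i], max(t$end[k]))
      o <- k[order(t$start[k])]
      expect_true(all(t$start[o][-1] == t$end[o][-length(o)]))
    }
  }
})

test_that("parse -> write -> parse round-trips 100 random trees", {
  corpus <- rand_corpus(100, seed = 7)
  txt <- write_ptb(corpus)
  again <- parse_ptb(txt)
  expect_identical(write_ptb(again), txt)
  expect_identical(length(again), 100L)
  for (k in c(1L, 50L, 100L)) {
    expect_identical(again[[k]]$tokens, corpus[[k]]$tokens)
    expect_identical(again[[k]]$role, corpus[[k]]$role)
    expect_identical(again[[k]]$pred, corpus[[k]]$pred)
  }
})

test_that("syntactic paths follow the worked examples", {
  fx <- fixture_sentences()
  ta <- fx$mining_a
  np <- which(ta$label == "NP" & ta$role == "ARG0" & !is.na(ta$role))
  expect_identical(syntactic_path(ta, np, ta$pred), "NP > S < VP < VBD")
  obj <- which(ta$label == "NP" & !is.na(ta$role) & ta$role == "ARG1")
  expect_identical(syntactic_path(ta, obj, ta$pred), "VBD > VP < NP")
  # a node to itself is just its own label
  expect_identical(syntactic_path(ta, np, np), "NP")
  # strict emission always writes `from` first
  expect_identical(syntactic_path(ta, ta$pred, np, order = "strict"),
                   "VBD > VP > S < NP")
  expect_error(syntactic_path(ta, 1L, 999L))
})

test_that("reversing a path reverses labels and flips every marker", {
  corpus <- rand_corpus(20, seed = 13)
  for (t in corpus) {
    nodes <- sample(seq_along(t$label), min(4L, length(t$label)))
    for (i in nodes) {
      fwd <- syntactic_path(t, i, t$pred, order = "strict")
      bwd <- syntactic_path(t, t$pred, i, order = "strict")
      expect_identical(reverse_path(fwd), bwd)
      p <- parse_path(fwd)
      expect_identical(p$labels[1], t$label[i])
      expect_identical(p$labels[length(p$labels)], t$label[t$pred])
    }
  }
})

test_that("props columns encode spans and round-trip", {
  tr <- parse_ptb("(S (NP-ARG0 (NN IL2) (NN receptor)) (VP (VBD-PRED bound) (NP (NN target))))")[[1]]
  txt <- write_props(list(tr), list(gold_assignment(tr)))
  rows <- strsplit(trimws(strsplit(txt, "\n")[[1]]), "\\s+")
  expect_identical(rows[[1]][2], "(ARG0*")
  expect_identical(rows[[2]][2], "*)")
  expect_identical(rows[[3]][1], "bind")

  empty <- write_props(list(tr), list(NULL))
  cells <- vapply(strsplit(trimws(strsplit(empty, "\n")[[1]]), "\\s+"),
                  `[`, character(1), 2L)
  expect_true(all(cells == "*"))

  corpus <- rand_corpus(25, seed = 3)
  gold <- lapply(corpus, gold_assignment)
  rt <- read_props(write_props(corpus, gold))
  expect_identical(length(rt), 25L)
  for (s in seq_along(corpus)) {
    got <- rt[[s]]$args[order(rt[[s]]$args$start), ]
    want <- args_of(corpus[s], gold[s])
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$role, want$role)
    expect_identical(rt[[s]]$pred_lemma, corpus[[s]]$pred_lemma)
  }
})

test_that("overlapping spans refuse to serialize", {
  tr <- parse_ptb("(S (NP (DT the) (NN gene)) (VP (VBD-PRED ran)))")[[1]]
  bad <- stats::setNames(c("ARG0", "ARG1"), c("1", "2"))  # S and NP overlap
  expect_error(write_props(list(tr), list(bad)), "overlap")
})
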