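# Scoring, exact collective decoding, MIRA learning.

test_that("local scores are linear in the weights", {
  w <- new_weights()
  feats <- c("ct=NP", "fw=the")
  expect_identical(score_local(w, feats, "ARG0"), 0)
  ids <- srlkit:::feat_ids(w, "ct=NP", add = TRUE)
  srlkit:::w_update(w, ids, "ARG0", 1.5)
  expect_identical(score_local(w, feats, "ARG0"), 1.5)
  expect_identical(score_local(w, feats, "ARG1"), 0)
  srlkit:::w_update(w, srlkit:::feat_ids(w, "fw=the", add = TRUE), "ARG0", 0.25)
  expect_identical(score_local(w, feats, "ARG0"), 1.75)
  # CI conjunction only fires for candidate roles
  srlkit:::w_update(w, srlkit:::feat_ids(w, "CI&ct=NP", add = TRUE), "ARG0", 2)
  expect_identical(score_local(w, feats, "ARG0", ci_roles = "ARG0", use_ci = TRUE), 3.75)
  expect_identical(score_local(w, feats, "ARG0", ci_roles = "ARG1", use_ci = TRUE), 1.75)
})

test_that("score matrices equal brute-force dot products over groundings", {
  corpus <- rand_corpus(5, seed = 71)
  t <- corpus[[1]]
  w <- new_weights()
  set.seed(72)
  # random weights over the features that actually occur
  feats <- unique(unlist(lapply(seq_along(t$label), function(i)
    extract_features(t, i))))
  roles <- c("ARG0", "ARG1", "ARGM-LOC")
  for (r in roles)
    srlkit:::w_update(w, srlkit:::feat_ids(w, sample(feats, 30), add = TRUE),
                      r, stats::rnorm(30))
  gp <- ground_problem(t, seq_along(t$label), roles, w)
  for (i in seq_along(t$label))
    for (r in roles)
      expect_equal(as.numeric(gp$scores[i, r]),
                   score_local(w, extract_features(t, i), r))
})

test_that("without binding constraints decoding is an independent argmax", {
  sc <- matrix(c(2, -1, 0.5,
                 -3, -2, -0.4), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("ARG0", "ARG1", "ARGM-LOC")))
  gp <- make_gp(sc, start = c(0L, 5L), end = c(2L, 7L))
  a <- collective_decode(gp, constraints = character(0))
  expect_identical(a, stats::setNames("ARG0", "1"))  # node 2 all-negative -> NONE
  b <- collective_decode(gp)
  expect_identical(b, a)                             # disjoint, distinct: same
})

test_that("duplicate core arguments collapse to the higher-scoring node", {
  sc <- matrix(c(2.0, 1.5), ncol = 1, dimnames = list(NULL, "ARG0"))
  gp <- make_gp(sc, start = c(0L, 4L), end = c(2L, 6L))
  a <- collective_decode(gp)
  expect_identical(a, stats::setNames("ARG0", "1"))
  # without the tree collective both get labeled
  expect_length(collective_decode(gp, constraints = character(0)), 2L)
})

test_that("overlapping favored nodes collapse to a single label", {
  sc <- matrix(c(2.0, 1.5), ncol = 1, dimnames = list(NULL, "ARG0"))
  gp <- make_gp(sc, start = c(0L, 0L), end = c(5L, 2L))  # ancestor/descendant
  a <- collective_decode(gp)
  expect_identical(a, stats::setNames("ARG0", "1"))
  gp2 <- make_gp(matrix(c(1.5, 2.0), ncol = 1, dimnames = list(NULL, "ARG0")),
                 start = c(0L, 0L), end = c(5L, 2L))
  expect_identical(collective_decode(gp2), stats::setNames("ARG0", "2"))
})

test_that("branch-and-bound and cutting-plane match exhaustive enumeration", {
  set.seed(73)
  for (k in 1:150) {
    gp <- rand_gp()
    ex <- collective_decode(gp, method = "exhaustive")
    for (m in c("bnb", "cutting")) {
      got <- collective_decode(gp, method = m)
      expect_equal(assignment_score(gp, got), assignment_score(gp, ex))
      expect_true(satisfies_constraints(gp, got))
    }
  }
})

test_that("MIRA updates follow the closed form and stop at zero loss", {
  roles <- "ARG0"
  sc <- matrix(c(0, 0), ncol = 1, dimnames = list(NULL, roles))
  gp <- make_gp(sc, start = c(0L, 4L), end = c(2L, 6L))
  gp$feats <- list("fw=the", "fw=a")
  gp$use_ci <- FALSE
  w <- new_weights()
  gold <- stats::setNames("ARG0", "1")
  # predicted == gold: no update
  tau0 <- mira_update(w, gold, gold, gp, C = Inf)
  expect_identical(tau0, 0)
  expect_identical(nrow(as.data.frame(w)), 0L)
  # one-node disagreement: loss 1, margin 0, ||dPhi||^2 = 1  =>  tau = 1
  tau <- mira_update(w, gold, stats::setNames(character(0), character(0)),
                     gp, C = Inf)
  expect_equal(tau, 1)
  d <- as.data.frame(w)
  expect_identical(d$feature, "fw=the")
  expect_equal(d$weight, 1)
  # after the update the example is scored correctly with a margin
  gp2 <- gp
  gp2$scores[1, 1] <- score_local(w, gp$feats[[1]], "ARG0")
  expect_true(gp2$scores[1, 1] >= 1)
  # the cap C clips the step
  w2 <- new_weights()
  tau2 <- mira_update(w2, gold, stats::setNames(character(0), character(0)),
                      gp, C = 0.01)
  expect_equal(tau2, 0.01)
})

test_that("training is reproducible and inert at C = 0", {
  corpus <- rand_corpus(12, seed = 79)
  m0 <- train_srl(corpus, config_local(epochs = 2, C = 0, seed = 5))
  expect_identical(nrow(as.data.frame(m0$weights)), 0L)
  cfg <- config_resource_saving(epochs = 2, seed = 9)
  m1 <- train_srl(corpus, cfg)
  m2 <- train_srl(corpus, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  save_weights(m1$weights, f1); save_weights(m2$weights, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a separable corpus is fit to zero training error within 10 epochs", {
  corpus <- generate_corpus(gen_config(20, seed = 5, signal = 1,
                                       distractor_prob = 0, overlap_prob = 0))
  m <- train_srl(corpus, config_resource_saving(epochs = 10, seed = 2))
  pred <- label_corpus(m, corpus)
  gold <- lapply(corpus, gold_assignment)
  rep <- conll_evaluate(gold, pred, gold_trees = corpus)
  expect_identical(rep$f[rep$role == "Overall"], 100)
})

test_that("every prediction satisfies the collective constraints", {
  corpus <- rand_corpus(40, seed = 83)
  m <- train_srl(corpus[1:25], config_resource_saving(epochs = 3, seed = 4))
  preds <- label_corpus(m, corpus[26:40])
  for (k in seq_along(preds)) {
    t <- corpus[[25 + k]]
    a <- preds[[k]]
    ids <- as.integer(names(a))
    core <- a[grepl("^ARG[0-5X]$", a)]
    expect_identical(anyDuplicated(core), 0L)
    if (length(ids) > 1L) {
      ov <- outer(t$start[ids], t$end[ids], "<") &
        outer(t$end[ids], t$start[ids], ">")
      diag(ov) <- FALSE
      expect_false(any(ov))
    }
  }
})

test_that("weights serialize, reload, and reject foreign roles", {
  corpus <- rand_corpus(8, seed = 89)
  m <- train_srl(corpus, config_local(epochs = 1, seed = 1))
  f <- tempfile()
  save_weights(m$weights, f)
  w2 <- load_weights(f, roles = m$roles)
  expect_identical(as.data.frame(m$weights), as.data.frame(w2))
  expect_error(load_weights(f, roles = "ARGM-TMP"), "outside the model")
})
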