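# F-scores, argument-wide and structure-wide evaluation, t-test protocol.

test_that("the F formula reproduces reported values and edge cases", {
  expect_identical(f_score(73.35, 71.95), 72.64)
  expect_identical(f_score(58.31, 58.31), 58.31)
  expect_identical(f_score(100, 0), 0)
  expect_identical(f_score(0, 0), 0)
  # monotone in each argument and bounded by the larger one
  expect_true(f_score(80, 60) < f_score(85, 60))
  expect_true(f_score(80, 60) < f_score(80, 65))
  expect_true(f_score(80, 60) <= 80)
})

test_that("argument-wide scoring counts exact span-and-label matches", {
  corpus <- rand_corpus(4, seed = 97)
  gold <- lapply(corpus, gold_assignment)
  perfect <- conll_evaluate(gold, gold, gold_trees = corpus)
  expect_true(all(perfect$precision == 100 & perfect$recall == 100 &
                    perfect$f == 100))

  # 4 gold arguments; predictions keep them and add one spurious
  g <- args_of(corpus, gold)[1:4, ]
  p <- rbind(g, data.frame(sentence = 1, start = 0, end = 1, role = "ARGM-TMP"))
  r <- conll_evaluate(g, p)
  ov <- r[r$role == "Overall", ]
  expect_identical(ov$precision, 80)
  expect_identical(ov$recall, 100)

  # corrupting one label costs exactly one argument on both sides
  fx <- fixture_sentences()
  ga <- gold_assignment(fx$mining_a)
  bad <- ga; bad[bad == "ARG1"] <- "ARG2"
  r2 <- conll_evaluate(list(ga), list(bad), gold_trees = list(fx$mining_a))
  ov2 <- r2[r2$role == "Overall", ]
  expect_identical(ov2$correct, 5L)
  expect_identical(ov2$gold, 6L)
  expect_identical(ov2$predicted, 6L)
  arg1 <- r2[r2$role == "ARG1", ]
  expect_identical(arg1$f, 0)
})

test_that("misaligned props inputs are rejected with a sentence index", {
  corpus <- rand_corpus(3, seed = 101)
  gold <- lapply(corpus, gold_assignment)
  gp <- read_props(write_props(corpus, gold))
  expect_error(conll_evaluate(gp, gp[1:2]), "sentence 3")
})

test_that("a structure counts only when all its arguments are exact", {
  corpus <- rand_corpus(10, seed = 103)
  gold <- lapply(corpus, gold_assignment)
  expect_identical(pas_evaluate(gold, gold, gold_trees = corpus)$f, 100)

  # corrupt one argument in every structure: structure-wide F collapses to 0
  crooked <- lapply(gold, function(a) { a[1] <- "ARGM-DSP"; a })
  r <- pas_evaluate(gold, crooked, gold_trees = corpus)
  expect_identical(r$f, 0)
  argwide <- conll_evaluate(gold, crooked, gold_trees = corpus)
  expect_true(argwide$f[argwide$role == "Overall"] > 0)

  # structure-correct implies every argument is argument-correct
  half <- gold
  half[[1]][1] <- "ARGM-DSP"
  rp <- pas_evaluate(gold, half, gold_trees = corpus)
  expect_identical(rp$correct, 9L)
})

test_that("structure-wide counts agree with a per-structure brute force", {
  set.seed(107)
  for (trial in 1:20) {
    corpus <- rand_corpus(8, seed = 1000 + trial)
    gold <- lapply(corpus, gold_assignment)
    pred <- lapply(gold, function(a) {
      a <- a[stats::runif(length(a)) > 0.2]           # drop some
      if (length(a) && stats::runif(1) < 0.3) a[1] <- "ARGM-CAU"  # corrupt
      a
    })
    r <- pas_evaluate(gold, pred, gold_trees = corpus)
    ok <- vapply(seq_along(corpus), function(s)
      identical(sort(paste(names(gold[[s]]), gold[[s]])),
                sort(paste(names(pred[[s]]), pred[[s]]))), logical(1))
    nonempty <- vapply(pred, length, integer(1)) > 0
    expect_identical(r$correct, sum(ok & nonempty))
    expect_identical(r$gold, length(corpus))
    expect_identical(r$predicted, sum(nonempty))
  }
})

test_that("the t statistic follows the printed formula and threshold", {
  a <- c(84.1, 85.2, 83.9, 84.8, 85.0)
  expect_identical(t_statistic(a, a)$t, 0)
  expect_false(t_statistic(a, a)$significant)

  # constant shift with equal SDs matches the closed form
  b <- a - 5
  tt <- t_statistic(a, b)
  expect_equal(tt$t, 5 / sqrt(2 * stats::sd(a)^2 / length(a)))
  expect_true(tt$significant)

  # the decision boundary is honored exactly at the critical value:
  # "equal to or less than 1.67" accepts the null hypothesis
  x0 <- c(1, -1, 1, -1)
  d <- 1.67 * stats::sd(x0) / 2            # mean shift giving t = 1.67
  t_at <- t_statistic(x0 + d, c(0, 0, 0, 0))
  expect_equal(t_at$t, 1.67)
  at_crit <- t_statistic(x0 + d, c(0, 0, 0, 0), critical = t_at$t)
  expect_false(at_crit$significant)
  above <- t_statistic(x0 + d + 0.1, c(0, 0, 0, 0))
  expect_true(above$t > 1.67 && above$significant)

  # paired variant
  expect_identical(t_statistic(a, a, paired = TRUE)$t, 0)
  expect_error(t_statistic(1, 1:3), "length")
})

test_that("resampling trains both systems on proportional partitions", {
  corpus <- rand_corpus(40, seed = 109)
  # stub systems: score = share of gold arguments, one system biased down
  sysA <- function(train, test) mean(lengths(lapply(test, gold_assignment)))
  sysB <- function(train, test) sysA(train, test) - 5
  r <- resampled_t_test(corpus, sysA, sysB, n_resamples = 6, seed = 11)
  expect_length(r$scores_a, 6L)
  expect_equal(r$scores_a - r$scores_b, rep(5, 6))
  expect_true(r$significant)
  same <- resampled_t_test(corpus, sysA, sysA, n_resamples = 6, seed = 11)
  expect_identical(same$t, 0)
  expect_error(resampled_t_test(corpus, sysA, sysB, n_resamples = 1), "2")
})
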