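# Argument-wide (CoNLL-style) and structure-wide precision/recall/F scoring,
# plus the resampled t-test comparison protocol.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Harmonic-mean F-score on the percent scale
#'
#' `F = 2 P R / (P + R)`, with `F = 0` when `P + R = 0`.
#'
#' @param precision,recall percentages in `[0, 100]`.
#' @param digits rounding (half-up) applied to the result; `NA` for none.
#' @return the F-score on the same scale.
#' @examples
#' f_score(73.35, 71.95)  # 72.64
#' @export
f_score <- function(precision, recall, digits = 2) {
  f <- ifelse(precision + recall == 0, 0,
              2 * precision * recall / (precision + recall))
  if (is.na(digits)) f else round_half_up(f, digits)
}

# normalize inputs to a data frame of arguments: sentence, start, end, role
as_args <- function(x, trees = NULL) {
  if (is.data.frame(x)) return(x)
  if (is.list(x) && length(x) && is.list(x[[1]]) && !is.null(x[[1]]$args)) {
    # read_props() output
    out <- do.call(rbind, lapply(seq_along(x), function(s) {
      a <- x[[s]]$args
      if (!nrow(a)) return(NULL)
      cbind(sentence = s, a)
    }))
    return(out %||% data.frame(sentence = integer(0), start = integer(0),
                               end = integer(0), role = character(0)))
  }
  # list of named assignments plus parallel trees
  stopifnot(!is.null(trees), length(x) == length(trees))
  rows <- lapply(seq_along(x), function(s) {
    a <- x[[s]]
    if (!length(a)) return(NULL)
    ids <- as.integer(names(a))
    data.frame(sentence = s, start = trees[[s]]$start[ids],
               end = trees[[s]]$end[ids], role = unname(a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(sentence = integer(0), start = integer(0),
                      end = integer(0), role = character(0))
}

#' Argument-wide CoNLL-style evaluation
#'
#' An argument is counted correct iff its token span and its role label both
#' match exactly.  Precision is correct/predicted, recall is correct/gold,
#' per role label and overall, on the percent scale.
#'
#' @param gold,predicted either data frames with columns `sentence`, `start`,
#'   `end`, `role`, outputs of [read_props()], or lists of node-indexed
#'   assignments (then supply `gold_trees`/`predicted_trees`).
#' @param gold_trees,predicted_trees tree lists used to resolve node-indexed
#'   assignments; `predicted_trees` defaults to `gold_trees`.
#' @param digits report rounding.
#' @return an `eval_report` data frame (one row per role plus `"Overall"`)
#'   with counts and `precision`, `recall`, `f` percentages.
#' @export
conll_evaluate <- function(gold, predicted, gold_trees = NULL,
                           predicted_trees = gold_trees, digits = 2) {
  is_props <- function(x) is.list(x) && !is.data.frame(x) && length(x) &&
    is.list(x[[1]]) && !is.null(x[[1]]$args)
  if (is_props(gold) && is_props(predicted) && length(gold) != length(predicted))
    stop("gold and predicted inputs are misaligned at sentence ",
         min(length(gold), length(predicted)) + 1L)
  g <- as_args(gold, gold_trees)
  p <- as_args(predicted, predicted_trees)
  gk <- paste(g$sentence, g$start, g$end, g$role)
  pk <- paste(p$sentence, p$start, p$end, p$role)
  roles <- sort(unique(c(g$role, p$role)))
  per <- lapply(c(roles, "Overall"), function(r) {
    gi <- if (r == "Overall") gk else gk[g$role == r]
    pi_ <- if (r == "Overall") pk else pk[p$role == r]
    correct <- sum(pi_ %in% gi)
    pr <- if (length(pi_)) 100 * correct / length(pi_) else 0
    rc <- if (length(gi)) 100 * correct / length(gi) else 0
    data.frame(role = r, gold = length(gi), predicted = length(pi_),
               correct = correct,
               precision = round_half_up(pr, digits),
               recall = round_half_up(rc, digits),
               f = f_score(pr, rc, digits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  class(out) <- c("eval_report", class(out))
  out
}

#' Structure-wide (PAS) evaluation
#'
#' A predicate-argument structure counts as correctly extracted only if every
#' gold argument of its predicate is predicted with exact span and label and
#' nothing spurious is predicted for it.  Precision divides by the number of
#' structures for which the system predicted at least one argument; recall by
#' the number of gold structures.
#'
#' @inheritParams conll_evaluate
#' @return an `eval_report` data frame with one `"PAS"` row.
#' @export
pas_evaluate <- function(gold, predicted, gold_trees = NULL,
                         predicted_trees = gold_trees, digits = 2) {
  g <- as_args(gold, gold_trees)
  p <- as_args(predicted, predicted_trees)
  sentences <- sort(unique(c(g$sentence, p$sentence)))
  keyset <- function(d, s) sort(paste(d$start[d$sentence == s],
                                      d$end[d$sentence == s],
                                      d$role[d$sentence == s]))
  gold_pas <- sentences[vapply(sentences, function(s)
    any(g$sentence == s), logical(1))]
  pred_pas <- sentences[vapply(sentences, function(s)
    any(p$sentence == s), logical(1))]
  correct <- sum(vapply(intersect(gold_pas, pred_pas), function(s)
    identical(keyset(g, s), keyset(p, s)), logical(1)))
  pr <- if (length(pred_pas)) 100 * correct / length(pred_pas) else 0
  rc <- if (length(gold_pas)) 100 * correct / length(gold_pas) else 0
  out <- data.frame(role = "PAS", gold = length(gold_pas),
                    predicted = length(pred_pas), correct = correct,
                    precision = round_half_up(pr, digits),
                    recall = round_half_up(rc, digits),
                    f = f_score(pr, rc, digits), stringsAsFactors = FALSE)
  class(out) <- c("eval_report", class(out))
  out
}

#' Two-sample t statistic on resampled scores
#'
#' `t = (mean(a) - mean(b)) / sqrt(sd(a)^2/n_a + sd(b)^2/n_b)` — the unpaired
#' statistic with the decision rule: the difference is significant when `t`
#' exceeds the critical value (default 1.67 at 29 degrees of freedom, the
#' protocol's stated threshold).  A paired variant is available.
#'
#' @param a,b numeric score vectors.
#' @param critical decision threshold.
#' @param df degrees of freedom reported.
#' @param paired use the paired statistic `mean(d)/ (sd(d)/sqrt(n))`?
#' @return a `t_test_result` list: `t`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `df`, `critical`, `significant`.
#' @export
t_statistic <- function(a, b, critical = 1.67, df = 29L, paired = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (paired) {
    stopifnot(length(a) == length(b))
    d <- a - b
    t <- if (stats::sd(d) == 0) 0 else mean(d) / (stats::sd(d) / sqrt(length(d)))
  } else {
    se <- sqrt(stats::sd(a)^2 / length(a) + stats::sd(b)^2 / length(b))
    t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  }
  structure(list(t = t, mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b), df = df,
                 critical = critical, significant = t > critical),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t = %.4f (df = %d); mean A = %.4f, mean B = %.4f; %s\n",
              x$t, x$df, x$mean_a, x$mean_b,
              if (x$significant) "difference significant (H0 rejected)"
              else "H0 accepted"))
  invisible(x)
}

#' Resampled comparison of two systems
#'
#' Draws `n_resamples` random train/test partitions of the corpus at the
#' protocol ratio (365:89 training:test units, scaled proportionally), trains
#' and evaluates both systems on each, and compares the resulting score
#' vectors with [t_statistic()].
#'
#' @param corpus list of `srl_tree`.
#' @param system_a,system_b functions `(train_corpus, test_corpus) -> score`.
#' @param n_resamples number of resamples (>= 2).
#' @param seed RNG seed.
#' @param ratio train fraction; default `365 / (365 + 89)`.
#' @param ... passed to [t_statistic()].
#' @return a `t_test_result` with the per-resample scores attached
#'   (`scores_a`, `scores_b`).
#' @export
resampled_t_test <- function(corpus, system_a, system_b, n_resamples = 30L,
                             seed = 1L, ratio = 365 / (365 + 89), ...) {
  if (n_resamples < 2L) stop("need at least 2 resamples")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  n <- length(corpus)
  ntr <- max(1L, min(n - 1L, round(n * ratio)))
  sa <- sb <- numeric(n_resamples)
  for (k in seq_len(n_resamples)) {
    tr <- sample.int(n, ntr)
    train <- corpus[tr]; test <- corpus[-tr]
    sa[k] <- system_a(train, test)
    sb[k] <- system_b(train, test)
  }
  out <- t_statistic(sa, sb, ...)
  out$scores_a <- sa; out$scores_b <- sb
  out
}
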