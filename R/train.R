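# 1-best MIRA online training of the collective labeler, and prediction.

#' Model configuration
#'
#' Selects the formula families and preprocessing of the three canonical
#' system variants: the discrete local system (`L` only), the collective
#' system (`L + C`) and the resource-saving collective system
#' (`RP + L + C + CI`).
#'
#' @param formulae subset of `c("L", "C", "CI")`: local formulae, collective
#'   constraints, candidate-identification formulae.
#' @param rp enable resource-saving preprocessing (tree-pruning filter plus
#'   candidate identifiers as a hard node filter)?
#' @param epochs passes of online learning.
#' @param C MIRA aggressiveness cap.
#' @param seed RNG seed controlling example shuffling.
#' @param average return averaged weights (recommended)?
#' @param decode_method see [collective_decode()].
#' @param prune a [prune_config()] used when `rp = TRUE`.
#' @param identifiers candidate identifiers enabled under `rp`/CI.
#' @param min_support,min_confidence,max_antecedent rule-mining thresholds.
#' @param items item pool for rule mining.
#' @return an `srl_config` list.
#' @export
srl_config <- function(formulae = c("L", "C", "CI"), rp = TRUE, epochs = 10L,
                       C = 0.01, seed = 1L, average = TRUE,
                       decode_method = "cutting", prune = prune_config(),
                       identifiers = c("ARCI", "WCI", "PCI", "PTCI"),
                       min_support = 0.001, min_confidence = 0.90,
                       max_antecedent = 4L,
                       items = c("FW", "LW", "CT", "PATH", "verb_predicate")) {
  stopifnot(all(formulae %in% c("L", "C", "CI")), "L" %in% formulae)
  structure(list(formulae = formulae, rp = rp, epochs = as.integer(epochs),
                 C = C, seed = as.integer(seed), average = average,
                 decode_method = decode_method, prune = prune,
                 identifiers = identifiers, min_support = min_support,
                 min_confidence = min_confidence,
                 max_antecedent = as.integer(max_antecedent), items = items),
            class = "srl_config")
}

#' Canonical configurations
#'
#' `config_local()` labels every node independently with local formulae only;
#' `config_collective()` adds the hard tree/path collective constraints;
#' `config_resource_saving()` additionally prunes and filters nodes through
#' the candidate identifiers and adds the CI formulae.
#'
#' @param ... overrides passed to [srl_config()].
#' @return an `srl_config`.
#' @export
config_local <- function(...) srl_config(formulae = "L", rp = FALSE, ...)

#' @rdname config_local
#' @export
config_collective <- function(...) srl_config(formulae = c("L", "C"), rp = FALSE, ...)

#' @rdname config_local
#' @export
config_resource_saving <- function(...)
  srl_config(formulae = c("L", "C", "CI"), rp = TRUE, ...)

# build the per-tree training/decoding instance under a configuration:
# eligible nodes, cached features, candidate roles
build_instance <- function(t, config, resources, ctx) {
  if (is.na(t$pred)) return(NULL)
  use_cand <- config$rp || "CI" %in% config$formulae
  if (config$rp) {
    surv <- apply_tpf(t, config$prune)
    cand <- identify_candidates(t, surv, resources, config$identifiers)
    nodes <- unique(cand$node)
  } else {
    # every node that could be an argument: spans not covering the predicate
    pt <- t$start[t$pred]
    nodes <- which(!(t$start <= pt & t$end > pt))
    cand <- if (use_cand)
      identify_candidates(t, nodes, resources, config$identifiers)
    else NULL
  }
  if (!length(nodes)) return(NULL)
  nodes <- sort(nodes)
  ci_roles <- if (use_cand)
    lapply(nodes, function(i) sort(unique(cand$role[cand$node == i])))
  else NULL
  feats <- lapply(nodes, function(i) extract_features(t, i, ctx))
  gold <- t$role[nodes]
  gold[is.na(gold)] <- "NONE"
  list(tree = t, nodes = nodes, feats = feats, ci_roles = ci_roles,
       gold = gold)
}

#' One 1-best MIRA update
#'
#' Applies `w <- w + tau * (Phi(gold) - Phi(predicted))` with
#' `tau = min(C, (loss - margin) / ||dPhi||^2)` clipped at 0, where the loss
#' is the Hamming distance between the two assignments over the problem's
#' nodes, the margin is `score(gold) - score(predicted)` under the current
#' weights, and `Phi` sums the (CI-expanded) feature vectors of the non-NONE
#' groundings.
#'
#' @param w an `srl_weights`, modified in place.
#' @param gold,predicted named role vectors over the problem's nodes.
#' @param gp the [ground_problem()] the prediction came from.
#' @param C aggressiveness cap (may be `Inf`).
#' @param u optional second weight store receiving `step * tau * dPhi`
#'   (the averaging accumulator).
#' @param step the 1-based global update counter (used with `u`).
#' @return the step size `tau`, invisibly.
#' @export
mira_update <- function(w, gold, predicted, gp, C = 0.01, u = NULL, step = 1L) {
  nodes <- gp$nodes
  glab <- role_at(gold, nodes); plab <- role_at(predicted, nodes)
  loss <- sum(glab != plab)
  if (loss == 0) return(invisible(0))
  margin <- assignment_score_by(gp, glab) - assignment_score_by(gp, plab)
  # sparse dPhi as (id, role, count)
  ids <- character(0); rs <- character(0); cnt <- numeric(0)
  for (k in seq_along(nodes)) {
    for (side in c(1, -1)) {
      r <- if (side == 1) glab[k] else plab[k]
      if (r == "NONE") next
      f <- gp$feats[[k]]
      if (gp$use_ci && r %in% gp$ci_roles[[k]]) f <- c(f, "CI", paste0("CI&", f))
      ids <- c(ids, f); rs <- c(rs, rep(r, length(f)))
      cnt <- c(cnt, rep(side, length(f)))
    }
  }
  if (!length(ids)) return(invisible(0))
  key <- paste0(ids, "\r", rs)
  agg <- rowsum(cnt, key)
  nz <- agg[, 1L] != 0
  if (!any(nz)) return(invisible(0))
  key <- rownames(agg)[nz]; cvec <- agg[nz, 1L]
  nrm2 <- sum(cvec^2)
  tau <- (loss - margin) / nrm2
  tau <- min(C, max(0, tau))
  if (tau > 0) {
    parts <- strsplit(key, "\r", fixed = TRUE)
    fs <- vapply(parts, `[`, character(1), 1L)
    rr <- vapply(parts, `[`, character(1), 2L)
    for (r in unique(rr)) {
      sel <- rr == r
      w_update(w, feat_ids(w, fs[sel], add = TRUE), r, tau * cvec[sel])
      if (!is.null(u))
        w_update(u, feat_ids(u, fs[sel], add = TRUE), r, step * tau * cvec[sel])
    }
  }
  invisible(tau)
}

role_at <- function(assignment, nodes) {
  out <- rep("NONE", length(nodes))
  if (length(assignment)) {
    pos <- match(as.integer(names(assignment)), nodes)
    out[pos[!is.na(pos)]] <- unname(assignment)[!is.na(pos)]
  }
  out
}

assignment_score_by <- function(gp, labs) {
  on <- which(labs != "NONE")
  if (!length(on)) return(0)
  sum(gp$scores[cbind(on, match(labs[on], gp$roles))])
}

#' Train the collective labeler
#'
#' Builds the configured resources from the training corpus (mined
#' association rules, the parse-path database, feature statistics), then runs
#' epochs of shuffled online 1-best MIRA with per-example collective
#' decoding; weights are averaged across updates.  Training is reproducible:
#' the same corpus, configuration and seed give identical weights.
#'
#' @param corpus list of `srl_tree` with gold roles.
#' @param config an [srl_config()].
#' @param quiet suppress progress output?
#' @return an `srl_model`.
#' @export
train_srl <- function(corpus, config = srl_config(), quiet = TRUE) {
  if (!length(corpus)) stop("cannot train on an empty corpus")
  use_cand <- config$rp || "CI" %in% config$formulae
  resources <- list(word_lists = wci_word_lists(), patterns = pci_patterns(),
                    items = config$items)
  if (use_cand) {
    resources$rules <- mine_rules(extract_transactions(corpus, config$items),
                                  config$min_support, config$min_confidence,
                                  config$max_antecedent)
    resources$path_db <- build_path_db(corpus)
  }
  ctx <- feature_context(corpus)
  roles <- sort(unique(unlist(lapply(corpus, function(t) t$role))))
  roles <- roles[!is.na(roles)]
  if (!length(roles)) stop("training corpus carries no gold roles")

  insts <- Filter(Negate(is.null),
                  lapply(corpus, build_instance, config, resources, ctx))
  infeasible <- 0L
  constraints <- if ("C" %in% config$formulae) c("unique_core", "no_overlap")
                 else character(0)
  use_ci <- "CI" %in% config$formulae

  w <- new_weights()
  u <- new_weights()                       # averaging accumulator
  step <- 0L
  # pre-check gold feasibility against the collective constraints
  for (ins in insts) {
    st <- ins$tree$start[ins$nodes]; en <- ins$tree$end[ins$nodes]
    ov <- outer(st, en, "<") & outer(en, st, ">")
    diag(ov) <- FALSE
    on <- which(ins$gold != "NONE")
    core_g <- ins$gold[on][ins$gold[on] %in% core_unique_roles(roles)]
    if (anyDuplicated(core_g) > 0L ||
        (length(on) > 1L && any(ov[on, on])))
      infeasible <- infeasible + 1L
  }
  if (infeasible)
    warning(infeasible, " training structure(s) violate the collective ",
            "constraints; trained on them anyway")

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(insts))
    ham <- 0L
    for (ix in ord) {
      ins <- insts[[ix]]
      gp <- gp_scores(ins$tree, ins$nodes, roles, w,
                      list(feats = ins$feats, ci_roles = ins$ci_roles), use_ci)
      pred <- collective_decode(gp, constraints, config$decode_method)
      gold <- stats::setNames(ins$gold[ins$gold != "NONE"],
                              ins$nodes[ins$gold != "NONE"])
      step <- step + 1L
      mira_update(w, gold, pred, gp, config$C,
                  u = if (config$average) u else NULL, step = step)
      ham <- ham + sum(role_at(gold, ins$nodes) != role_at(pred, ins$nodes))
    }
    if (!quiet) message("epoch ", ep, ": training hamming loss ", ham)
  }

  weights <- w
  if (config$average && step > 0L) weights <- averaged_weights(w, u, step)
  structure(list(weights = weights, raw_weights = w, roles = roles, ctx = ctx,
                 resources = resources, config = config,
                 n_train = length(insts)),
            class = "srl_model")
}

# Averaging uses the standard lazy trick: along with each update tau*dPhi to
# w, u receives step*tau*dPhi; the average over all update-prefix snapshots
# is then w - u/total.
averaged_weights <- function(w, u, total) {
  avg <- new_weights()
  d <- as.data.frame(w)
  if (!nrow(d)) return(avg)
  du <- as.data.frame(u)
  key <- paste0(d$feature, "\r", d$role)
  uval <- stats::setNames(du$weight, paste0(du$feature, "\r", du$role))
  adj <- d$weight - ifelse(key %in% names(uval), uval[key], 0) / total
  for (r in unique(d$role)) {
    sel <- d$role == r
    w_update(avg, feat_ids(avg, d$feature[sel], add = TRUE), r, adj[sel])
  }
  avg
}

#' Label trees with a trained model
#'
#' @param model an `srl_model` from [train_srl()].
#' @param trees an `srl_tree` or list of them.
#' @return a list of named role vectors (node index -> role), one per tree.
#' @export
label_corpus <- function(model, trees) {
  if (inherits(trees, "srl_tree")) trees <- list(trees)
  config <- model$config
  constraints <- if ("C" %in% config$formulae) c("unique_core", "no_overlap")
                 else character(0)
  use_ci <- "CI" %in% config$formulae
  lapply(trees, function(t) {
    ins <- build_instance(t, config, model$resources, model$ctx)
    if (is.null(ins)) return(stats::setNames(character(0), character(0)))
    gp <- gp_scores(ins$tree, ins$nodes, model$roles, model$weights,
                    list(feats = ins$feats, ci_roles = ins$ci_roles), use_ci)
    collective_decode(gp, constraints, config$decode_method)
  })
}

#' @export
print.srl_model <- function(x, ...) {
  cat("<srl_model> ", paste(x$config$formulae, collapse = "+"),
      if (x$config$rp) " +RP", "; ", length(x$roles), " roles; trained on ",
      x$n_train, " structures\n", sep = "")
  invisible(x)
}
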