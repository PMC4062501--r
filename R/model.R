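# The collective labeling model: a log-linear per-(node, role) scorer with
# hard collective constraints, exact MAP decoding (branch-and-bound, with an
# exhaustive oracle mode and a lazy cutting-plane mode), 1-best MIRA online
# learning with weight averaging, and the three formula families as
# configuration: L (local), C (collective constraints), CI (candidate
# identification features), plus the resource-saving preprocessing switch RP.

# ---- weights ----------------------------------------------------------------
#
# Weights map (feature, role) pairs to reals; missing entries read as 0.
# Internally features are interned into an integer dictionary and each role
# owns a dense numeric vector, which keeps scoring a vectorized subset-sum.

#' Create an empty weight store
#' @return an `srl_weights` object.
#' @export
new_weights <- function() {
  e <- new.env(parent = emptyenv())
  e$dict <- new.env(hash = TRUE, parent = emptyenv())
  e$nfeat <- 0L
  e$W <- new.env(hash = TRUE, parent = emptyenv())
  structure(list(e = e), class = "srl_weights")
}

# intern feature strings -> integer ids; add = grow the dictionary
feat_ids <- function(w, features, add = FALSE) {
  if (!length(features)) return(integer(0))
  ids <- unlist(mget(features, envir = w$e$dict, ifnotfound = NA_integer_),
                use.names = FALSE)
  if (add && anyNA(ids)) {
    miss <- which(is.na(ids))
    for (k in miss) {
      f <- features[k]
      got <- get0(f, envir = w$e$dict, ifnotfound = NA_integer_)
      if (is.na(got)) {
        w$e$nfeat <- w$e$nfeat + 1L
        got <- w$e$nfeat
        assign(f, got, envir = w$e$dict)
      }
      ids[k] <- got
    }
  }
  ids
}

role_vec <- function(w, role) get0(role, envir = w$e$W, ifnotfound = numeric(0))

# weight values for feature ids under one role (NA ids and unseen ids read 0)
w_lookup <- function(w, ids, role) {
  vec <- role_vec(w, role)
  out <- numeric(length(ids))
  ok <- !is.na(ids) & ids <= length(vec)
  out[ok] <- vec[ids[ok]]
  out
}

w_update <- function(w, ids, role, delta) {
  keep <- !is.na(ids)
  ids <- ids[keep]
  if (length(delta) > 1L) delta <- delta[keep]
  if (!length(ids)) return(invisible(w))
  vec <- role_vec(w, role)
  if (length(vec) < w$e$nfeat) vec <- c(vec, numeric(w$e$nfeat - length(vec)))
  agg <- rowsum(rep(delta, length.out = length(ids)), ids)
  at <- as.integer(rownames(agg))
  vec[at] <- vec[at] + agg[, 1L]
  assign(role, vec, envir = w$e$W)
  invisible(w)
}

#' Convert weights to a sorted data frame
#' @param x an `srl_weights`; @param ... unused.
#' @return data frame with columns `feature`, `role`, `weight` (zeros
#'   dropped), sorted by feature then role.
#' @export
as.data.frame.srl_weights <- function(x, ...) {
  feats <- ls(x$e$dict)
  ids <- unlist(mget(feats, envir = x$e$dict), use.names = FALSE)
  lut <- character(x$e$nfeat)
  lut[ids] <- feats
  rows <- list()
  for (r in ls(x$e$W)) {
    vec <- get(r, envir = x$e$W)
    nz <- which(vec != 0)
    if (length(nz))
      rows[[r]] <- data.frame(feature = lut[nz], role = r, weight = vec[nz],
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(feature = character(0), role = character(0),
                      weight = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$feature, out$role), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize weights as sorted tab-separated text
#' @param w an `srl_weights`; @param file a path.
#' @export
save_weights <- function(w, file) {
  d <- as.data.frame(w)
  d$weight <- sprintf("%.17g", d$weight)   # full double precision round-trip
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Restore weights from tab-separated text
#' @param file a path written by [save_weights()].
#' @param roles optional known role inventory; rows naming other roles are
#'   rejected.
#' @return an `srl_weights`.
#' @export
load_weights <- function(file, roles = NULL) {
  d <- utils::read.table(file, sep = "\t", header = TRUE, quote = "",
                         stringsAsFactors = FALSE, comment.char = "")
  if (!is.null(roles) && !all(d$role %in% roles))
    stop("weight file names roles outside the model inventory: ",
         paste(unique(setdiff(d$role, roles)), collapse = ", "))
  w <- new_weights()
  for (r in unique(d$role)) {
    sel <- d$role == r
    ids <- feat_ids(w, d$feature[sel], add = TRUE)
    w_update(w, ids, r, d$weight[sel])
  }
  w
}

#' Score one node's features for one role
#'
#' The sum of the weights of all `(feature, role)` pairs; when candidate
#' identification (CI) formulae are enabled and `role` is among the node's
#' candidate roles, each feature is additionally conjoined with the candidate
#' fact (features prefixed `CI&`, plus a bare `CI` indicator) and those
#' weights are added too.
#'
#' @param w an `srl_weights`.
#' @param features `name=value` strings from [extract_features()].
#' @param role a role label.
#' @param ci_roles candidate roles recorded for this node (or `NULL`).
#' @param use_ci are CI formulae enabled?
#' @return a numeric score.
#' @export
score_local <- function(w, features, role, ci_roles = NULL, use_ci = FALSE) {
  s <- sum(w_lookup(w, feat_ids(w, features), role))
  if (use_ci && role %in% ci_roles)
    s <- s + sum(w_lookup(w, feat_ids(w, c("CI", paste0("CI&", features))), role))
  s
}

# ---- ground problems --------------------------------------------------------

#' Build the ground decoding problem for one tree
#'
#' Collects the candidate `(node, role)` groundings with their local scores
#' and the constraint structure: the at-most-one-role-per-node constraint is
#' implicit in the assignment representation; the tree collective limits each
#' core role to one node; the path collective forbids two overlapping labeled
#' nodes (overlap = span intersection, which on one parse tree means
#' domination).
#'
#' @param t an `srl_tree` with a predicate.
#' @param nodes node indices eligible for labeling.
#' @param roles role inventory (columns of the score matrix).
#' @param w an `srl_weights`.
#' @param feats optional precomputed feature-vector list parallel to `nodes`.
#' @param ci_roles optional list of candidate-role vectors parallel to `nodes`.
#' @param use_ci enable CI formulae in scoring.
#' @param ctx optional [feature_context()].
#' @return a `ground_problem`: list with `nodes`, `roles`, `scores`
#'   (nodes x roles matrix), `overlap` (logical matrix), `start`, `depth`,
#'   plus cached features for learning.
#' @export
ground_problem <- function(t, nodes, roles, w, feats = NULL, ci_roles = NULL,
                           use_ci = FALSE, ctx = NULL) {
  if (is.null(feats)) feats <- lapply(nodes, function(i) extract_features(t, i, ctx))
  inst <- list(feats = feats, ci_roles = ci_roles)
  gp_scores(t, nodes, roles, w, inst, use_ci)
}

# scoring core shared by ground_problem() and the training loop; `inst` may
# carry interned ids (ids, ci_ids) to avoid re-interning each epoch
gp_scores <- function(t, nodes, roles, w, inst, use_ci) {
  n <- length(nodes)
  scores <- matrix(0, n, length(roles), dimnames = list(NULL, roles))
  if (n) {
    all_f <- unlist(inst$feats, use.names = FALSE)
    idx <- rep(seq_len(n), lengths(inst$feats))
    all_ids <- feat_ids(w, all_f)
    ci_f <- ci_idx <- NULL
    if (use_ci && !is.null(inst$ci_roles)) {
      has_any <- lengths(inst$ci_roles) > 0L
      sel <- has_any[idx]
      ci_f <- c("CI", paste0("CI&", all_f[sel]))
      ci_idx <- c(0L, idx[sel])              # 0 marks the bare indicator
      ci_ids <- feat_ids(w, ci_f)
    }
    for (r in roles) {
      v <- w_lookup(w, all_ids, r)
      scores[, r] <- rowsum_safe(v, idx, n)
      if (use_ci && !is.null(inst$ci_roles)) {
        has <- vapply(inst$ci_roles, function(cr) r %in% cr, logical(1))
        if (any(has)) {
          vv <- w_lookup(w, ci_ids, r)
          base <- vv[1L]
          add <- rowsum_safe(vv[-1L], ci_idx[-1L], n)
          scores[, r] <- scores[, r] + ifelse(has, add + base, 0)
        }
      }
    }
  }
  st <- t$start[nodes]; en <- t$end[nodes]
  ov <- outer(st, en, "<") & outer(en, st, ">")
  if (n) diag(ov) <- FALSE
  structure(list(tree = t, nodes = nodes, roles = roles, scores = scores,
                 overlap = ov, start = st, depth = node_depth(t, nodes),
                 feats = inst$feats, ci_roles = inst$ci_roles, use_ci = use_ci),
            class = "ground_problem")
}

rowsum_safe <- function(v, idx, n) {
  out <- numeric(n)
  if (length(v)) {
    s <- rowsum(v, idx)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

# ---- decoding ---------------------------------------------------------------

#' Collective MAP decoding
#'
#' Finds the label assignment maximizing the summed local scores subject to
#' the enabled hard constraints: (a) at most one role per node (always), (b)
#' at most one node per core role, (c) no two overlapping labeled nodes.  The
#' `NONE` label has fixed score 0, so with (b) and (c) disabled decoding
#' reduces to an independent per-node argmax with a `NONE` threshold at 0.
#'
#' Methods: `"bnb"` — exact depth-first branch-and-bound with an admissible
#' suffix bound; `"exhaustive"` — full enumeration (for small problems and
#' testing); `"cutting"` — cutting-plane search that starts unconstrained and
#' lazily adds violated uniqueness/overlap constraints until the solution is
#' feasible.  All methods return an optimal assignment; ties are broken
#' deterministically (nodes in span/depth order, `NONE` preferred on a score
#' tie, then roles by score and lexicographically).
#'
#' @param gp a [ground_problem()].
#' @param constraints subset of `c("unique_core", "no_overlap")`.
#' @param method decoding method.
#' @return named character vector: role per labeled node index (`NONE`
#'   omitted).
#' @export
collective_decode <- function(gp, constraints = c("unique_core", "no_overlap"),
                              method = c("cutting", "bnb", "exhaustive")) {
  method <- match.arg(method)
  if (!length(gp$nodes)) return(stats::setNames(character(0), character(0)))
  ord <- order(gp$start, gp$depth)
  sol <- switch(method,
    bnb = decode_bnb(gp, ord, constraints),
    exhaustive = decode_exhaustive(gp, ord, constraints),
    cutting = decode_cutting(gp, ord, constraints))
  lab <- sol$labels
  keep <- lab > 0L
  stats::setNames(gp$roles[lab[keep]], gp$nodes[ord][keep])
}

#' Objective value of an assignment
#' @param gp a [ground_problem()]; @param assignment named role vector.
#' @return summed local score.
#' @export
assignment_score <- function(gp, assignment) {
  if (!length(assignment)) return(0)
  pos <- match(as.integer(names(assignment)), gp$nodes)
  sum(gp$scores[cbind(pos, match(unname(assignment), gp$roles))])
}

core_unique_roles <- function(roles) roles[grepl("^ARG[0-5X]$", roles)]

# option order for one node: by score descending, NONE preferred on ties,
# then role name
option_order <- function(sc, roles) {
  opts <- c(0L, seq_along(roles))
  val <- c(0, sc)
  none_last <- c(0L, rep(1L, length(roles)))
  opts[order(-val, none_last, c("", roles))]
}

decode_bnb <- function(gp, ord, constraints, active_pairs = NULL,
                       active_roles = NULL) {
  sc <- gp$scores[ord, , drop = FALSE]
  n <- nrow(sc); roles <- gp$roles
  uniq_on <- "unique_core" %in% constraints
  ov_on <- "no_overlap" %in% constraints
  ov <- gp$overlap[ord, ord, drop = FALSE]
  lazy_pairs <- !is.null(active_pairs)
  if (lazy_pairs && length(active_pairs)) {
    ov2 <- matrix(FALSE, n, n)
    for (p in active_pairs) { ov2[p[1], p[2]] <- TRUE; ov2[p[2], p[1]] <- TRUE }
    ov <- ov2
  } else if (lazy_pairs) {
    ov_on <- FALSE
  }
  core <- if (uniq_on) {
    if (is.null(active_roles)) core_unique_roles(roles) else active_roles
  } else character(0)
  core_idx <- match(core, roles)

  gain <- pmax(0, apply(sc, 1, max))
  suffix <- c(rev(cumsum(rev(gain)))[-1], 0)

  env <- new.env(parent = emptyenv())
  env$best_val <- -Inf
  env$best_lab <- integer(n)
  labels <- integer(n)
  labeled <- logical(n)
  used_core <- logical(length(roles))
  opt_orders <- lapply(seq_len(n), function(i) option_order(sc[i, ], roles))

  rec <- function(i, cur) {
    if (i > n) {
      if (cur > env$best_val) { env$best_val <- cur; env$best_lab <- labels }
      return(invisible())
    }
    if (cur + suffix[i] + gain[i] <= env$best_val) return(invisible())
    for (o in opt_orders[[i]]) {
      if (o > 0L) {
        if (uniq_on && o %in% core_idx && used_core[o]) next
        if (ov_on && any(labeled & ov[, i])) next
        labels[i] <<- o
        labeled[i] <<- TRUE
        if (o %in% core_idx) used_core[o] <<- TRUE
        rec(i + 1L, cur + sc[i, o])
        if (o %in% core_idx) used_core[o] <<- FALSE
        labeled[i] <<- FALSE
        labels[i] <<- 0L
      } else {
        rec(i + 1L, cur)
      }
    }
    invisible()
  }
  rec(1L, 0)
  list(labels = env$best_lab, value = env$best_val)
}

decode_exhaustive <- function(gp, ord, constraints) {
  sc <- gp$scores[ord, , drop = FALSE]
  n <- nrow(sc); roles <- gp$roles
  ov <- gp$overlap[ord, ord, drop = FALSE]
  uniq_on <- "unique_core" %in% constraints
  ov_on <- "no_overlap" %in% constraints
  core_idx <- match(core_unique_roles(roles), roles)
  opt_orders <- lapply(seq_len(n), function(i) option_order(sc[i, ], roles))
  env <- new.env(parent = emptyenv())
  env$best_val <- -Inf; env$best_lab <- integer(n)
  labels <- integer(n)
  rec <- function(i, cur) {
    if (i > n) {
      if (uniq_on) {
        cu <- labels[labels %in% core_idx]
        if (anyDuplicated(cu)) return(invisible())
      }
      if (ov_on) {
        on <- which(labels > 0L)
        if (length(on) > 1L && any(ov[on, on])) return(invisible())
      }
      if (cur > env$best_val) { env$best_val <- cur; env$best_lab <- labels }
      return(invisible())
    }
    for (o in opt_orders[[i]]) {
      labels[i] <<- o
      rec(i + 1L, cur + if (o > 0L) sc[i, o] else 0)
    }
    labels[i] <<- 0L
    invisible()
  }
  rec(1L, 0)
  list(labels = env$best_lab, value = env$best_val)
}

decode_cutting <- function(gp, ord, constraints) {
  sc <- gp$scores[ord, , drop = FALSE]
  n <- nrow(sc); roles <- gp$roles
  ov <- gp$overlap[ord, ord, drop = FALSE]
  core_idx <- match(core_unique_roles(roles), roles)
  active_roles <- character(0)
  active_pairs <- list()
  repeat {
    sol <- if (!length(active_roles) && !length(active_pairs)) {
      lab <- vapply(seq_len(n), function(i) opt_first(sc[i, ], roles), integer(1))
      val <- sum(vapply(seq_len(n), function(i)
        if (lab[i] > 0L) sc[i, lab[i]] else 0, numeric(1)))
      list(labels = lab, value = val)
    } else {
      decode_bnb(gp, ord,
                 constraints = c(if (length(active_roles)) "unique_core",
                                 if (length(active_pairs)) "no_overlap"),
                 active_pairs = active_pairs, active_roles = active_roles)
    }
    lab <- sol$labels
    viol <- FALSE
    if ("unique_core" %in% constraints) {
      cu <- lab[lab %in% core_idx]
      dup <- unique(cu[duplicated(cu)])
      newr <- setdiff(roles[dup], active_roles)
      if (length(newr)) { active_roles <- c(active_roles, newr); viol <- TRUE }
    }
    if ("no_overlap" %in% constraints) {
      on <- which(lab > 0L)
      if (length(on) > 1L) {
        pr <- which(ov[on, on, drop = FALSE], arr.ind = TRUE)
        pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE]
        for (r in seq_len(nrow(pr))) {
          pair <- sort(c(on[pr[r, 1]], on[pr[r, 2]]))
          is_new <- !any(vapply(active_pairs, function(p) all(p == pair),
                                logical(1)))
          if (is_new) {
            active_pairs[[length(active_pairs) + 1L]] <- pair
            viol <- TRUE
          }
        }
      }
    }
    if (!viol) return(sol)
  }
}

opt_first <- function(sc, roles) {
  b <- max(sc)
  if (b <= 0) return(0L)
  cand <- which(sc == b)
  cand[order(roles[cand])][1]
}

#' Check an assignment against the collective constraints
#'
#' @param gp a [ground_problem()].
#' @param assignment named role vector as returned by [collective_decode()].
#' @return `TRUE` iff no core role is used twice and no two labeled nodes
#'   overlap (one role per node holds by construction).
#' @export
satisfies_constraints <- function(gp, assignment) {
  ids <- as.integer(names(assignment))
  pos <- match(ids, gp$nodes)
  if (anyNA(pos)) return(FALSE)
  core <- assignment[assignment %in% core_unique_roles(gp$roles)]
  if (anyDuplicated(core)) return(FALSE)
  if (length(pos) > 1L && any(gp$overlap[pos, pos])) return(FALSE)
  TRUE
}
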