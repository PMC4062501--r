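#' Annotated constituency parse trees
#'
#' An `srl_tree` stores one constituency parse of one sentence together with a
#' marked verb predicate and (optionally) gold PropBank-style role labels on
#' nodes.  Nodes are kept in preorder in parallel vectors; token coordinates
#' are 0-based half-open intervals `[start, end)`.
#'
#' Fields:
#' \describe{
#'   \item{label}{constituent or POS tag per node}
#'   \item{parent}{parent node index (`NA` for the root)}
#'   \item{children}{list of child index vectors, in surface order}
#'   \item{word}{surface token for terminals, `NA` for internal nodes}
#'   \item{start,end}{token span per node}
#'   \item{role}{gold role label per node or `NA`}
#'   \item{tokens}{the sentence as an ordered token vector}
#'   \item{pred}{index of the verb-predicate terminal (or `NA`)}
#'   \item{pred_lemma}{lemma of the verb predicate}
#' }
#'
#' @param label,parent,word,start,end,role,tokens,pred,pred_lemma see above.
#' @return an object of class `srl_tree`.
#' @keywords internal
new_srl_tree <- function(label, parent, word, start, end, role, tokens,
                         pred = NA_integer_, pred_lemma = NA_character_) {
  children <- vector("list", length(label))
  kid <- which(!is.na(parent))
  if (length(kid)) {
    sp <- split(kid, parent[kid])
    children[as.integer(names(sp))] <- lapply(sp, function(k) k[order(start[k])])
  }
  t <- structure(
    list(label = label, parent = parent, children = children, word = word,
         start = start, end = end, role = role, tokens = tokens,
         pred = pred, pred_lemma = pred_lemma),
    class = "srl_tree")
  validate_srl_tree(t)
  t
}

#' Validate srl_tree invariants
#'
#' Checks that internal spans tile their children exactly, that terminal spans
#' have width one, that sibling spans are disjoint and ordered, that the
#' predicate (if any) is a terminal, and that the predicate carries no gold
#' role.
#'
#' @param t an `srl_tree`.
#' @return `t`, invisibly; errors on violation.
#' @export
validate_srl_tree <- function(t) {
  n <- length(t$label)
  stopifnot(length(t$parent) == n, length(t$word) == n,
            length(t$start) == n, length(t$end) == n, length(t$role) == n)
  term <- !is.na(t$word)
  if (any(t$end[term] - t$start[term] != 1L))
    stop("terminal spans must have width 1")
  for (i in which(!term)) {
    k <- t$children[[i]]
    if (!length(k)) stop("internal node ", i, " has no children")
    if (t$start[i] != min(t$start[k]) || t$end[i] != max(t$end[k]))
      stop("span of node ", i, " does not equal the union of its children")
    o <- k[order(t$start[k])]
    if (any(t$start[o][-1] != t$end[o][-length(o)]))
      stop("children of node ", i, " do not tile its span")
  }
  if (sum(is.na(t$parent)) != 1L) stop("tree must have exactly one root")
  if (!is.na(t$pred)) {
    if (is.na(t$word[t$pred])) stop("predicate node must be a terminal")
    if (!is.na(t$role[t$pred])) stop("the predicate node cannot carry a gold role")
  }
  invisible(t)
}

n_nodes <- function(t) length(t$label)

tree_root <- function(t) which(is.na(t$parent))

is_terminal <- function(t, i = seq_along(t$label)) !is.na(t$word[i])

#' Node depth (root = 0)
#' @param t an `srl_tree`; @param i node indices.
#' @return integer depths.
#' @keywords internal
node_depth <- function(t, i) {
  vapply(i, function(j) {
    d <- 0L
    while (!is.na(t$parent[j])) { j <- t$parent[j]; d <- d + 1L }
    d
  }, integer(1))
}

ancestors_of <- function(t, i) {
  out <- integer(0)
  while (!is.na(t$parent[i])) { i <- t$parent[i]; out <- c(out, i) }
  out
}

subtree_nodes <- function(t, i) {
  out <- i
  frontier <- t$children[[i]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(t$children[frontier], use.names = FALSE)
  }
  sort(out)
}

#' Surface text of a node's span
#' @param t an `srl_tree`; @param i node index; @param collapse separator.
#' @return the span's tokens pasted together.
#' @export
span_text <- function(t, i, collapse = " ") {
  paste(t$tokens[(t$start[i] + 1L):t$end[i]], collapse = collapse)
}

#' Gold argument nodes of a tree
#' @param t an `srl_tree`.
#' @return integer node indices carrying gold roles.
#' @export
gold_nodes <- function(t) which(!is.na(t$role))

#' @export
print.srl_tree <- function(x, ...) {
  cat("<srl_tree> ", length(x$tokens), " tokens, ", n_nodes(x), " nodes\n", sep = "")
  cat("  sentence: ", paste(x$tokens, collapse = " "), "\n", sep = "")
  if (!is.na(x$pred))
    cat("  predicate: ", x$word[x$pred], " [", x$pred_lemma, "] at token ",
        x$start[x$pred], "\n", sep = "")
  g <- gold_nodes(x)
  if (length(g))
    cat("  gold roles: ",
        paste(sprintf("%s=%s(\"%s\")", x$role[g], x$label[g],
                      vapply(g, function(i) span_text(x, i), character(1))),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- role labels ------------------------------------------------------------

.role_rx <- "^(C-|R-)?ARG([0-5X]|M-[A-Z]+)$"

#' Role label classification
#'
#' Core roles are `ARG0`--`ARG5`, `ARGX` and their `R-`/`C-` variants; adjunct
#' roles carry the `ARGM-` prefix.
#'
#' @param role character vector of role names.
#' @return logical vector.
#' @export
is_core_role <- function(role) grepl("^(C-|R-)?ARG[0-5X]$", role)

#' @rdname is_core_role
#' @export
is_adjunct_role <- function(role) grepl("^ARGM-", role)

#' @rdname is_core_role
#' @export
is_valid_role <- function(role) grepl(.role_rx, role)
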