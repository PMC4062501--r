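#' Syntactic path between two nodes
#'
#' The path walks from one endpoint up to the lowest common ancestor and down
#' to the other, writing node labels joined by direction markers: `>` steps to
#' a parent, `<` steps to a child.  With `order = "surface"` (the default) the
#' endpoint whose span starts earlier in the sentence is written first, which
#' is the convention of the worked rule-mining examples; `order = "strict"`
#' always writes `from` first.
#'
#' @param t an `srl_tree`.
#' @param from,to node indices.
#' @param order `"surface"` or `"strict"`.
#' @return the path as a single string, e.g. `"NP > S < VP < VBD"`.
#' @examples
#' tr <- parse_ptb("(S (NP (NN T3)) (VP (VBD-PRED induced)))")[[1]]
#' syntactic_path(tr, which(tr$label == "NP"), tr$pred)
#' @export
syntactic_path <- function(t, from, to, order = c("surface", "strict")) {
  order <- match.arg(order)
  stopifnot(from >= 1L, from <= n_nodes(t), to >= 1L, to <= n_nodes(t))
  if (order == "surface" &&
      (t$start[to] < t$start[from] ||
       (t$start[to] == t$start[from] && node_depth(t, to) < node_depth(t, from)))) {
    tmp <- from; from <- to; to <- tmp
  }
  if (from == to) return(t$label[from])
  up <- c(from, ancestors_of(t, from))
  dn <- c(to, ancestors_of(t, to))
  lca <- intersect(up, dn)[1]
  if (is.na(lca)) stop("nodes are not in the same tree")
  upseq <- up[seq_len(match(lca, up))]          # from ... lca
  dnseq <- rev(dn[seq_len(match(lca, dn))])     # lca ... to
  paste0(paste(t$label[upseq], collapse = " > "),
         if (length(dnseq) > 1L)
           paste0(" < ", paste(t$label[dnseq[-1]], collapse = " < ")))
}

#' Parse a path string back into labels and directions
#'
#' @param path a path string as produced by [syntactic_path()].
#' @return a list with `labels` (character) and `dirs` (character, `">"`/`"<"`,
#'   one shorter than `labels`).
#' @export
parse_path <- function(path) {
  parts <- strsplit(trimws(path), "\\s+")[[1]]
  odd <- seq(1L, length(parts), by = 2L)
  list(labels = parts[odd],
       dirs = if (length(parts) > 1L) parts[seq(2L, length(parts), by = 2L)]
              else character(0))
}

#' Reverse a path string
#'
#' Reversing endpoints reverses the label sequence and flips every marker.
#' @param path a path string.
#' @return the reversed path string.
#' @export
reverse_path <- function(path) {
  p <- parse_path(path)
  if (!length(p$dirs)) return(path)
  flipped <- rev(ifelse(p$dirs == ">", "<", ">"))
  labs <- rev(p$labels)
  out <- labs[1]
  for (k in seq_along(flipped)) out <- paste(out, flipped[k], labs[k + 1L])
  out
}
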