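#' Write predictions in CoNLL-style props column format
#'
#' One block per (tree, predicate), blank-line separated.  Each block has one
#' row per token: column 1 holds the predicate lemma on the predicate token
#' and `-` elsewhere; column 2 holds the bracketed role spans, `(ROLE*` at a
#' span start, `*)` at a span end, `(ROLE*)` for width-one spans and `*` in
#' between / outside.
#'
#' @param trees list of `srl_tree`.
#' @param assignments list parallel to `trees`; each element a named character
#'   vector mapping node index (as name) to role, or `NULL` for no arguments.
#'   Use [gold_assignment()] to export the gold annotation.
#' @param file optional output path.
#' @return the props text (invisibly when `file` is given).
#' @export
write_props <- function(trees, assignments, file = NULL) {
  if (inherits(trees, "srl_tree")) trees <- list(trees)
  stopifnot(length(trees) == length(assignments))
  blocks <- mapply(function(t, a) {
    nt <- length(t$tokens)
    col1 <- rep("-", nt)
    if (!is.na(t$pred)) col1[t$start[t$pred] + 1L] <- t$pred_lemma
    col2 <- rep("*", nt)
    opens <- rep("", nt); closes <- rep("", nt)
    if (length(a)) {
      ids <- as.integer(names(a))
      sp <- data.frame(start = t$start[ids], end = t$end[ids], role = unname(a))
      sp <- sp[order(sp$start), , drop = FALSE]
      if (nrow(sp) > 1L && any(sp$start[-1] < sp$end[-nrow(sp)]))
        stop("overlapping role spans cannot be serialized to props columns")
      for (r in seq_len(nrow(sp))) {
        opens[sp$start[r] + 1L] <- paste0("(", sp$role[r])
        closes[sp$end[r]] <- ")"
      }
      col2 <- paste0(opens, "*", closes)
    }
    paste(paste(format(col1, width = 12L), col2), collapse = "\n")
  }, trees, assignments)
  txt <- paste(paste(blocks, collapse = "\n\n"), "\n", sep = "")
  if (!is.null(file)) { writeLines(txt, file, sep = ""); return(invisible(txt)) }
  txt
}

#' Read props column text
#'
#' @param text props text (or a file path with `is_file = TRUE`).
#' @param is_file read `text` as a path?
#' @return a list with one element per block: `list(pred_lemma, pred_token,
#'   args)` where `args` is a data frame with columns `start`, `end`, `role`
#'   (0-based half-open token spans).
#' @export
read_props <- function(text, is_file = FALSE) {
  lines <- if (is_file) readLines(text, warn = FALSE)
           else strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  lines <- sub("\\s+$", "", lines)
  groups <- split(lines, cumsum(lines == ""))
  groups <- lapply(groups, function(g) g[g != ""])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  lapply(groups, function(g) {
    parts <- strsplit(trimws(g), "\\s+")
    col1 <- vapply(parts, `[`, character(1), 1L)
    col2 <- vapply(parts, `[`, character(1), 2L)
    pred_tok <- which(col1 != "-") - 1L
    args <- data.frame(start = integer(0), end = integer(0), role = character(0))
    open_role <- NA_character_; open_at <- NA_integer_
    for (i in seq_along(col2)) {
      cell <- col2[i]
      m <- regmatches(cell, regexpr("^\\(([^*)]+)", cell))
      if (length(m) && nzchar(m)) {
        if (!is.na(open_role)) stop("nested span opened at row ", i)
        open_role <- sub("^\\(", "", m); open_at <- i - 1L
      }
      if (grepl("\\)$", cell)) {
        if (is.na(open_role)) stop("unmatched span close at row ", i)
        args <- rbind(args, data.frame(start = open_at, end = i, role = open_role))
        open_role <- NA_character_
      }
    }
    if (!is.na(open_role)) stop("span left open at end of block")
    list(pred_lemma = if (length(pred_tok)) col1[pred_tok + 1L] else NA_character_,
         pred_token = if (length(pred_tok)) pred_tok[1] else NA_integer_,
         args = args)
  })
}

#' Gold annotation of a tree as a props assignment
#'
#' @param t an `srl_tree`.
#' @return a named character vector mapping node index to gold role.
#' @export
gold_assignment <- function(t) {
  g <- gold_nodes(t)
  stats::setNames(t$role[g], g)
}
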