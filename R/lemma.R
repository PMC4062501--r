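# Verb lemmatization and word stemming.
#
# The predicate lemmatizer is table-first: regular inflections of the bundled
# biomedical verb lexicon (the kind of frequent event verbs a proposition bank
# covers) are generated at load time, a few irregulars are added, and a
# suffix-stripping fallback handles unseen verbs.  Word stems used for
# first/last-word items are deliberately lighter: lower-casing plus plural
# stripping only, so "cells" -> "cell" but "overcoming" is left intact.

#' Biomedical verb lexicon
#'
#' Thirty frequent molecular-event verb lemmas, the default predicate
#' inventory of the synthetic corpus generator.
#' @return a character vector of lemmas.
#' @export
verb_lexicon <- function() c(
  "activate", "affect", "associate", "bind", "block", "contain", "decrease",
  "encode", "enhance", "express", "increase", "induce", "inhibit", "interact",
  "mediate", "modulate", "mutate", "phosphorylate", "prevent", "promote",
  "reduce", "regulate", "repress", "require", "signal", "stimulate",
  "suppress", "transcribe", "translate", "trigger")

# regular inflected forms of a lemma: -s, -ed, -ing (with final-e handling)
inflect_verb <- function(lemma) {
  stem <- sub("e$", "", lemma)
  s3 <- if (grepl("(s|x|z|ch|sh)$", lemma)) paste0(lemma, "es") else paste0(lemma, "s")
  unique(c(s3, paste0(stem, "ed"), paste0(stem, "ing")))
}

.inflection_table <- local({
  lemmas <- verb_lexicon()
  tab <- c()
  for (l in lemmas) {
    forms <- inflect_verb(l)
    tab[forms] <- l
    tab[l] <- l
  }
  # irregulars seen in biomedical prose
  irr <- c(bound = "bind", binding = "bind", overcame = "overcome",
           overcoming = "overcome", overcome = "overcome",
           was = "be", were = "be", is = "be", are = "be", been = "be",
           being = "be", am = "be", got = "get", gotten = "get",
           encodes = "encode", induced = "induce", expressed = "express")
  tab[names(irr)] <- irr
  tab
})

#' Lemmatize a verb form
#'
#' Table lookup over the bundled inflection table with a suffix-stripping
#' fallback (`-ies` -> `-y`, `-es`/`-ed`/`-ing`/`-s` stripped, restoring a
#' final `e` when the bare stem ends in a non-doubling consonant cluster).
#'
#' @param word a verb form.
#' @param extra optional named character vector of additional form -> lemma
#'   entries consulted first.
#' @return the lemma, lower-cased.
#' @examples
#' lemmatize_verb("induced")   # "induce"
#' lemmatize_verb("expressed") # "express"
#' @export
lemmatize_verb <- function(word, extra = NULL) {
  w <- tolower(word)
  if (!is.null(extra) && w %in% names(extra)) return(unname(extra[w]))
  if (w %in% names(.inflection_table)) return(unname(.inflection_table[w]))
  if (grepl("ied$", w)) return(sub("ied$", "y", w))
  if (grepl("ies$", w)) return(sub("ies$", "y", w))
  for (suf in c("ing", "ed", "es", "s")) {
    if (grepl(paste0(suf, "$"), w) && nchar(w) > nchar(suf) + 2L) {
      stem <- sub(paste0(suf, "$"), "", w)
      # undo consonant doubling ("stopped" -> "stop")
      nc <- nchar(stem)
      if (nc >= 2L && substr(stem, nc, nc) == substr(stem, nc - 1L, nc - 1L) &&
          grepl("[^aeiou]$", stem))
        stem <- substr(stem, 1L, nc - 1L)
      # restore final e for -ed/-ing on e-final stems ("induc" -> "induce")
      if (suf %in% c("ing", "ed") && grepl("[^aeiouy][cgsvz]$|[aeiou][ct]$", stem))
        stem <- paste0(stem, "e")
      return(stem)
    }
  }
  w
}

#' Stem a surface word for first/last-word items
#'
#' Lower-cases and strips plural morphology only: `-ies` -> `-y`, `-xes` /
#' `-ses` / `-zes` / `-ches` / `-shes` lose `es`, other final `-s` is dropped
#' unless the word ends in `ss`, `us` or `is`.
#'
#' @param word character vector of tokens.
#' @return stemmed tokens.
#' @examples
#' word_stem(c("cells", "thus", "overcoming"))
#' @export
word_stem <- function(word) {
  w <- tolower(word)
  out <- w
  i <- grepl("ies$", w) & nchar(w) > 4L
  out[i] <- sub("ies$", "y", w[i])
  j <- !i & grepl("(x|s|z|ch|sh)es$", w)
  out[j] <- sub("es$", "", w[j])
  k <- !i & !j & grepl("s$", w) & !grepl("(ss|us|is)$", w) & nchar(w) > 3L
  out[k] <- sub("s$", "", w[k])
  out
}
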