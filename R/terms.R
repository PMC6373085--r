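the_term_dictionary <- new.env(parent = emptyenv())

#' The shipped term synonym dictionary
#'
#' Maps normalized free-text variants ("DM2", "Type II Diabetes Mellitus") to
#' canonical condition tokens. Users can pass their own dictionary (a tibble
#' with `variant`, `token`) to [normalize_term()].
#'
#' @return Tibble with columns `variant` (already normalized) and `token`.
#' @export
term_dictionary <- function() {
  if (is.null(the_term_dictionary$dict)) {
    path <- system.file("extdata", "term_dictionary.csv", package = "emrdq")
    d <- readr::read_csv(path, show_col_types = FALSE)
    d$variant <- normalize_text(d$variant)
    the_term_dictionary$dict <- d
  }
  the_term_dictionary$dict
}

# Lexical normalization only: lowercase, punctuation to space, squish.
normalize_text <- function(text) {
  text <- tolower(as.character(text))
  text <- stringr::str_replace_all(text, "[[:punct:]]+", " ")
  stringr::str_squish(text)
}

#' Normalize a free-text clinical term
#'
#' Lowercases, collapses punctuation and whitespace, then maps the result
#' through a synonym dictionary so that spelling variants of the same concept
#' ("DM2", "diabetes mellitus type 2") yield the same token. Unmatched text is
#' returned in its lexically normalized form; empty input yields an empty
#' token that matches nothing.
#'
#' @param text Character vector of free text.
#' @param dictionary Synonym dictionary tibble (`variant`, `token`); defaults
#'   to the shipped [term_dictionary()].
#' @return Character vector of normalized tokens.
#' @examples
#' normalize_term(c("Type II Diabetes Mellitus", "DM2", "hay fever"))
#' @export
normalize_term <- function(text, dictionary = term_dictionary()) {
  norm <- normalize_text(text)
  hit <- match(norm, dictionary$variant)
  out <- ifelse(is.na(hit), norm, dictionary$token[hit])
  out[is.na(text)] <- ""
  out
}
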