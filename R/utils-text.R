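# Text normalization shared by terminology matching, featurization and the
# fixture search backend. Lookups against the vocabulary are surface-level:
# lowercase, punctuation stripped, whitespace collapsed — never stemmed.

#' Normalize a term for vocabulary matching
#'
#' Lowercases, replaces punctuation with spaces and collapses whitespace.
#' This is the canonical form used for all terminology lookups; stemming is
#' deliberately not applied here because concept names are matched on their
#' surface form.
#'
#' @param x Character vector.
#' @return Character vector of normalized terms.
#' @export
normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Tokenize text on whitespace
#'
#' @param x A single string.
#' @return Character vector of raw tokens (possibly empty).
#' @export
tokenize_ws <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# cached stopword set
.ebm_env <- new.env(parent = emptyenv())

#' English stopword list
#'
#' Returns the packaged English stopword list (Snowball-style) used by the
#' free-text PICO pipeline and the data-feature tokenizer.
#'
#' @return Character vector of lowercase stopwords.
#' @export
ebm_stopwords <- function() {
  if (is.null(.ebm_env$stopwords)) {
    path <- ebm_extdata("config", "stopwords.txt")
    words <- readLines(path, warn = FALSE)
    .ebm_env$stopwords <- words[nzchar(words) & !startsWith(words, "#")]
  }
  .ebm_env$stopwords
}

# Abbreviations that must not terminate a sentence.
.sentence_abbrev <- c(
  "e.g", "i.e", "etc", "vs", "al", "fig", "dr", "mr", "mrs", "ms", "no",
  "st", "approx", "ca", "cf"
)

#' Split text into sentences
#'
#' Rule-based splitter: breaks after terminal punctuation (`.`, `?`, `!`)
#' followed by whitespace, guarded against a list of common abbreviations
#' (e.g., "et al.", "e.g.", "Fig.").
#'
#' @param text A single string.
#' @return Character vector of sentences, in document order.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  # candidate break points: terminal punctuation followed by space
  pos <- gregexpr("[.?!]+(?=\\s)", text, perl = TRUE)[[1]]
  if (pos[1] == -1L) return(text)
  lens <- attr(pos, "match.length")
  keep <- logical(length(pos))
  for (i in seq_along(pos)) {
    before <- substr(text, 1L, pos[i] - 1L)
    last_word <- tolower(sub("^.*?([A-Za-z.]+)$", "\\1", before))
    last_word <- sub("\\.$", "", last_word)
    keep[i] <- !(last_word %in% .sentence_abbrev)
  }
  pos <- pos[keep]; lens <- lens[keep]
  if (length(pos) == 0L) return(text)
  starts <- c(1L, pos + lens)
  ends <- c(pos + lens - 1L, nchar(text))
  out <- substring(text, starts, ends)
  out <- trimws(out)
  out[nzchar(out)]
}

# Data-feature token pipeline: whitespace tokens -> lowercase -> stopword
# removal -> Porter stem -> length filter.
feature_tokens <- function(text, min_len = 2L, max_len = 25L) {
  toks <- normalize_term(tokenize_ws(text))
  toks <- as.character(unlist(strsplit(toks, " "), use.names = FALSE))
  toks <- toks[nzchar(toks)]
  toks <- toks[!(toks %in% ebm_stopwords())]
  toks <- porter_stem(toks)
  toks[nchar(toks) >= min_len & nchar(toks) <= max_len]
}

# Metadata token pipeline: tokenization and case folding only.
meta_tokens <- function(strings) {
  toks <- as.character(unlist(strsplit(normalize_term(strings), " "),
                              use.names = FALSE))
  toks[nzchar(toks)]
}
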