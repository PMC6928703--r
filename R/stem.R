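# Porter stemming algorithm (Porter 1980), original rule set. Implemented
# here because the suffix-stripping step of the feature pipeline needs it and
# the package carries its own text-processing primitives.
#
# Conventions: a "consonant" is any letter other than a, e, i, o, u, and
# other than y when preceded by a consonant. The measure m of a stem counts
# VC sequences in its [C](VC){m}[V] form.

# TRUE at position i if letter i of `chars` is a consonant.
.porter_is_cons <- function(chars) {
  n <- length(chars)
  vowels <- c("a", "e", "i", "o", "u")
  cons <- !(chars %in% vowels)
  if (n > 1L) {
    for (i in 2L:n) {
      if (chars[i] == "y") cons[i] <- !cons[i - 1L]
    }
  }
  if (n >= 1L && chars[1L] == "y") cons[1L] <- TRUE
  cons
}

# measure m of a stem (string)
.porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cons <- .porter_is_cons(strsplit(stem, "")[[1]])
  # count V-to-C transitions
  m <- 0L
  prev_vowel <- FALSE
  for (ci in cons) {
    if (ci && prev_vowel) m <- m + 1L
    prev_vowel <- !ci
  }
  m
}

.porter_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.porter_is_cons(strsplit(stem, "")[[1]]))
}

# *d: stem ends with a double consonant
.porter_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L); b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  cons <- .porter_is_cons(strsplit(stem, "")[[1]])
  cons[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  cons <- .porter_is_cons(strsplit(stem, "")[[1]])
  if (!(cons[n - 2L] && !cons[n - 1L] && cons[n])) return(FALSE)
  !(substr(stem, n, n) %in% c("w", "x", "y"))
}

.ends_with <- function(w, suf) {
  nchar(w) > nchar(suf) && substring(w, nchar(w) - nchar(suf) + 1L) == suf
}

.chop <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))

# Apply the longest matching suffix rule from a list(suffix = replacement)
# table, guarded by a measure condition on the stem. Only the longest
# matching suffix is considered; if its condition fails nothing happens.
.porter_rule_table <- function(w, table, min_m) {
  sufs <- names(table)
  sufs <- sufs[order(nchar(sufs), decreasing = TRUE)]
  for (suf in sufs) {
    if (.ends_with(w, suf)) {
      stem <- .chop(w, suf)
      if (.porter_m(stem) > min_m) {
        return(paste0(stem, table[[suf]]))
      }
      return(w)
    }
  }
  w
}

.porter_stem1 <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # Step 1a
  if (.ends_with(w, "sses")) {
    w <- .chop(w, "es")
  } else if (.ends_with(w, "ies")) {
    w <- paste0(.chop(w, "ies"), "i")
  } else if (.ends_with(w, "ss")) {
    # unchanged
  } else if (.ends_with(w, "s")) {
    w <- .chop(w, "s")
  }

  # Step 1b
  step1b_fired <- FALSE
  if (.ends_with(w, "eed")) {
    stem <- .chop(w, "eed")
    if (.porter_m(stem) > 0L) w <- .chop(w, "d")
  } else if (.ends_with(w, "ed") && .porter_has_vowel(.chop(w, "ed"))) {
    w <- .chop(w, "ed"); step1b_fired <- TRUE
  } else if (.ends_with(w, "ing") && .porter_has_vowel(.chop(w, "ing"))) {
    w <- .chop(w, "ing"); step1b_fired <- TRUE
  }
  if (step1b_fired) {
    if (.ends_with(w, "at") || .ends_with(w, "bl") || .ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.porter_m(w) == 1L && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # Step 1c
  if (.ends_with(w, "y") && .porter_has_vowel(.chop(w, "y"))) {
    w <- paste0(.chop(w, "y"), "i")
  }

  # Step 2 (m > 0)
  w <- .porter_rule_table(w, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), min_m = 0L)

  # Step 3 (m > 0)
  w <- .porter_rule_table(w, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""
  ), min_m = 0L)

  # Step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  sufs4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  sufs4 <- sufs4[order(nchar(sufs4), decreasing = TRUE)]
  for (suf in sufs4) {
    if (.ends_with(w, suf)) {
      stem <- .chop(w, suf)
      ok <- .porter_m(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # Step 5a
  if (.ends_with(w, "e")) {
    stem <- .chop(w, "e")
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) w <- stem
  }

  # Step 5b
  if (.porter_m(w) > 1L && .porter_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1L, nchar(w) - 1L)
  }

  w
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter (1980)
#' suffix-stripping algorithm (original rule set). Words of one or two
#' letters, and tokens containing non-alphabetic characters, are returned
#' unchanged apart from case folding.
#'
#' @param words Character vector of words.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("running", "studies", "caresses", "relational"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  words <- tolower(words)
  cache <- .stem_cache()
  uniq <- unique(words)
  todo <- uniq[!vapply(uniq, function(w) !is.null(cache[[w]]), logical(1))]
  for (w in todo) {
    cache[[w]] <- if (!grepl("^[a-z]+$", w)) w else .porter_stem1(w)
  }
  vapply(words, function(w) cache[[w]], character(1), USE.NAMES = FALSE)
}

# per-session memo of word -> stem (the algorithm is pure)
.stem_cache <- function() {
  if (is.null(.ebm_env$stem_cache)) {
    .ebm_env$stem_cache <- new.env(parent = emptyenv(), hash = TRUE)
  }
  .ebm_env$stem_cache
}
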