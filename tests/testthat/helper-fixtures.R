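# Shared fixtures, memoized so expensive corpora are built once per run.

.fix_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix_env[[key]])) .fix_env[[key]] <- force(expr)
  .fix_env[[key]]
}

demo_store <- function() memo("demo_store", make_terminology_fixture())

# benchmark corpus at the study conditions (high separation, n = 2000,
# seed 7), split 0.7 and vectorized
high_bench <- function() memo("high_bench", {
  corpus <- make_synthetic_corpus(
    corpus_spec(n_articles = 2000, separation = "high", seed = 7))
  parts <- split_corpus(corpus, ratio = 0.7, seed = 7)
  train <- vectorize_corpus(parts$train)
  test <- vectorize_corpus(parts$test, vocabulary = train$vocabulary)
  list(corpus = corpus, parts = parts, train = train, test = test)
})

# a small/medium-separation corpus for paired-learner comparisons
medium_bench <- function(seed = 5) memo(paste0("medium_", seed), {
  corpus <- make_synthetic_corpus(
    corpus_spec(n_articles = 400, separation = "medium", seed = seed))
  parts <- split_corpus(corpus, ratio = 0.7, seed = seed)
  train <- vectorize_corpus(parts$train)
  test <- vectorize_corpus(parts$test, vocabulary = train$vocabulary)
  list(parts = parts, train = train, test = test)
})

# Independent brute-force STI oracle: scans every concept name and synonym
# directly, re-deriving level, weight and tie-breaks from first principles.
sti_bruteforce <- function(term, store) {
  norm_term <- normalize_term(term)
  concepts <- store$concepts
  best <- list(level = "none", weight = 0, id = NA_character_, nchar = -1L)
  consider <- function(level, id, key) {
    weight <- c(exact = 1, synonym = 0.5, partial = 0.5)[[level]]
    rank <- c(exact = 1, synonym = 2, partial = 3)[[level]]
    cur_rank <- c(exact = 1, synonym = 2, partial = 3, none = 4)[[best$level]]
    kn <- nchar(key)
    better <- rank < cur_rank ||
      (rank == cur_rank && (kn > best$nchar ||
                            (kn == best$nchar && id < best$id)))
    if (better) {
      best <<- list(level = level, weight = weight, id = id, nchar = kn)
    }
  }
  tokens_of <- function(x) unique(strsplit(x, " ")[[1]])
  tt <- tokens_of(norm_term)
  is_partial <- function(key) {
    kt <- tokens_of(key)
    shared <- intersect(tt, kt)
    if (!any(nchar(shared) >= 4)) return(FALSE)
    (length(tt) < length(kt) && all(tt %in% kt)) ||
      (length(kt) < length(tt) && all(kt %in% tt))
  }
  for (i in seq_len(nrow(concepts))) {
    id <- concepts$concept_id[i]
    pn <- normalize_term(concepts$preferred_name[i])
    if (pn == norm_term) consider("exact", id, pn)
    for (syn in normalize_term(concepts$synonyms[[i]])) {
      if (syn == norm_term) consider("synonym", id, syn)
    }
    for (key in c(pn, normalize_term(concepts$synonyms[[i]]))) {
      if (is_partial(key)) consider("partial", id, key)
    }
  }
  best
}

# tiny article tibble builder
make_article <- function(id, title = "", abstract = "",
                         mesh = character(0), ptypes = character(0),
                         journal = "J", year = 2020L) {
  tibble::tibble(article_id = id, title = title, abstract = abstract,
                 mesh_terms = list(mesh), publication_types = list(ptypes),
                 journal = journal, year = as.integer(year))
}
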