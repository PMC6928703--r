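# Extractive PICO-scaffold summarization. Secondary studies (systematic
# reviews, meta-analyses) are evidence in themselves and keep only their
# meta information; primary studies get per-element extractive summaries:
# each abstract sentence is scored per PICO element by the summed STI
# weights of its matched concepts (C folds into I — a comparison is itself
# an intervention), attributed to every element whose score exceeds the
# threshold, and the top-k sentences per element are kept in document
# order. Summaries are then grouped into evidence by single-linkage over
# Jaccard similarity of their token sets.

.secondary_types <- c("systematic review", "meta analysis",
                      "meta analysis of rcts", "meta analysis of cts",
                      "systematic review of cts")

#' Triage an article as a primary or secondary study
#'
#' Secondary when any publication type indicates a synthesis study
#' (systematic review or meta-analysis, including their subtypes); primary
#' otherwise. Secondary dominates when both kinds of types are listed.
#'
#' @param publication_types Character vector of publication-type strings.
#' @return `"primary"` or `"secondary"`.
#' @export
triage <- function(publication_types) {
  norm <- normalize_term(publication_types %||% character(0))
  if (any(norm %in% .secondary_types)) "secondary" else "primary"
}

#' Extract PICO-element sentences from an article
#'
#' Splits the abstract into sentences; each sentence is scanned for
#' candidate n-grams, matched with [sti_match()] and slotted with
#' [assign_slot()]. A sentence's score for an element is the sum of STI
#' weights of its concepts assigned to that element (C counts toward I);
#' the sentence is attributed to every element whose score exceeds
#' `threshold`, and the `top_k` highest-scoring sentences per element are
#' returned in document order. Empty text yields empty lists.
#'
#' @param title,abstract Article text fields.
#' @param store A [terminology_store()].
#' @param mapping Slot-mapping table.
#' @param threshold Minimum element score for attribution (default 0:
#'   any positively scored sentence qualifies).
#' @param top_k Sentences kept per element (default 3).
#' @return List with character vectors `p_sentences`, `i_sentences`,
#'   `o_sentences` — each a subset of the abstract's sentences.
#' @export
extract_pio <- function(title, abstract, store, mapping = slot_mapping(),
                        threshold = 0, top_k = 3L) {
  stopifnot(inherits(store, "terminology_store"))
  empty <- list(p_sentences = character(0), i_sentences = character(0),
                o_sentences = character(0))
  if (!nzchar(trimws(paste(title, abstract)))) return(empty)
  sentences <- split_sentences(abstract)
  if (!length(sentences)) return(empty)

  scores <- matrix(0, nrow = length(sentences), ncol = 3,
                   dimnames = list(NULL, c("P", "I", "O")))
  for (si in seq_along(sentences)) {
    tokens <- normalize_term(tokenize_ws(sentences[si]))
    tokens <- unlist(strsplit(tokens, " "), use.names = FALSE)
    tokens <- tokens[nzchar(tokens) & !(tokens %in% ebm_stopwords())]
    if (!length(tokens)) next
    cands <- .scan_candidates(tokens, store)
    for (ci in seq_len(nrow(cands))) {
      con <- .concept_row(store, cands$concept_id[ci])
      slot <- suppressWarnings(
        assign_slot(con, mapping, have_intervention = FALSE))
      if (slot == "C") slot <- "I"
      scores[si, slot] <- scores[si, slot] + cands$weight[ci]
    }
  }
  pick <- function(col) {
    hit <- which(scores[, col] > threshold)
    if (length(hit) > top_k) {
      hit <- hit[order(-scores[hit, col])][seq_len(top_k)]
      hit <- sort(hit)   # back to document order
    }
    sentences[hit]
  }
  list(p_sentences = pick("P"), i_sentences = pick("I"),
       o_sentences = pick("O"))
}

#' Summarize one article
#'
#' Primary studies get the extractive PIO scaffold of [extract_pio()] and a
#' combined summary (the P, I and O element summaries concatenated in that
#' order); secondary studies are processed only for their meta information.
#'
#' @param record One-row article tibble.
#' @param store A [terminology_store()].
#' @param ... Passed to [extract_pio()].
#' @return An `article_summary` object.
#' @export
summarize_article <- function(record, store, ...) {
  record <- tibble::as_tibble(record)
  stopifnot(nrow(record) == 1L)
  kind <- triage(record$publication_types[[1]])
  if (kind == "secondary") {
    pio <- list(p_sentences = character(0), i_sentences = character(0),
                o_sentences = character(0))
  } else {
    pio <- extract_pio(record$title, record$abstract, store, ...)
  }
  structure(list(
    article_id = record$article_id,
    study_kind = kind,
    p_sentences = pio$p_sentences,
    i_sentences = pio$i_sentences,
    o_sentences = pio$o_sentences,
    combined = paste(c(pio$p_sentences, pio$i_sentences, pio$o_sentences),
                     collapse = " "),
    meta = list(publication_types = record$publication_types[[1]],
                year = record$year, journal = record$journal)
  ), class = "article_summary")
}

#' @export
print.article_summary <- function(x, ...) {
  cat(sprintf("<article_summary %s (%s): %d P / %d I / %d O sentences>\n",
              x$article_id, x$study_kind, length(x$p_sentences),
              length(x$i_sentences), length(x$o_sentences)))
  invisible(x)
}

.jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Group article summaries into evidence
#'
#' Single-linkage grouping over pairwise Jaccard similarity of the
#' combined-summary token sets: two summaries join one evidence group when
#' their similarity is at least `threshold`, directly or through a chain.
#' The groups partition the input.
#'
#' @param summaries List of `article_summary` objects.
#' @param threshold Similarity threshold in (0, 1].
#' @return Tibble with `article_id`, `study_kind`, `group` (integer id) and
#'   `meta` (list column).
#' @export
group_evidence <- function(summaries, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- length(summaries)
  if (n == 0L) {
    return(tibble::tibble(article_id = character(), study_kind = character(),
                          group = integer(), meta = list()))
  }
  toksets <- lapply(summaries, function(s) unique(feature_tokens(s$combined)))
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (.jaccard(toksets[[i]], toksets[[j]]) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  group <- match(roots, unique(roots))
  tibble::tibble(
    article_id = vapply(summaries, `[[`, character(1), "article_id"),
    study_kind = vapply(summaries, `[[`, character(1), "study_kind"),
    group = as.integer(group),
    meta = lapply(summaries, `[[`, "meta")
  )
}
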