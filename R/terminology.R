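# Controlled-vocabulary store and the weighted salient-term-identification
# (STI) matcher. Matching levels: an exact match on a preferred name scores
# w = 1.0; a whole-name synonym match and a token-subset partial match score
# w = 0.5; no match scores 0. Precedence is exact > synonym > partial.

#' Construct a terminology store from a concept table
#'
#' @param concepts A data frame with columns `concept_id`, `preferred_name`,
#'   `synonyms` (list of character vectors), `semantic_types` (list),
#'   `entity_type` (character) and `parent_ids` (list).
#' @return A `terminology_store` object: the concept tibble plus a
#'   normalized name/synonym index.
#' @export
terminology_store <- function(concepts) {
  concepts <- tibble::as_tibble(concepts)
  required <- c("concept_id", "preferred_name", "synonyms", "semantic_types",
                "entity_type", "parent_ids")
  missing_cols <- setdiff(required, names(concepts))
  if (length(missing_cols)) {
    abort(sprintf("concept table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(concepts$concept_id)) {
    dup <- concepts$concept_id[duplicated(concepts$concept_id)][1]
    abort(sprintf("duplicate concept_id in terminology: '%s'", dup),
          class = "ebm_integrity_error")
  }
  if (any(!nzchar(concepts$preferred_name))) {
    abort("every concept needs a non-empty preferred_name",
          class = "ebm_integrity_error")
  }
  all_parents <- unique(unlist(concepts$parent_ids, use.names = FALSE))
  dangling <- setdiff(all_parents, concepts$concept_id)
  if (length(dangling)) {
    abort(sprintf("dangling parent_id(s): %s",
                  paste(dangling, collapse = ", ")),
          class = "ebm_integrity_error")
  }

  idx <- purrr::pmap_dfr(
    list(concepts$concept_id, concepts$preferred_name, concepts$synonyms),
    function(id, name, syns) {
      keys <- c(name, syns %||% character(0))
      kinds <- c("preferred", rep("synonym", length(keys) - 1L))
      tibble::tibble(
        key = normalize_term(keys),
        concept_id = id,
        kind = kinds,
        key_nchar = nchar(normalize_term(keys))
      )
    }
  )
  structure(
    list(concepts = concepts, index = idx),
    class = "terminology_store"
  )
}

#' @export
print.terminology_store <- function(x, ...) {
  cat(sprintf("<terminology_store: %d concepts, %d indexed names>\n",
              nrow(x$concepts), nrow(x$index)))
  invisible(x)
}

#' Number of concepts in a terminology store
#' @param x A `terminology_store`.
#' @param ... Unused.
#' @export
length.terminology_store <- function(x) nrow(x$concepts)

#' Load a terminology store from a JSON fixture
#'
#' The fixture is a JSON array of objects with fields `id`, `name`,
#' `synonyms`, `semantic_types`, `entity_type` and `parents`.
#'
#' @param path Path to the JSON file.
#' @return A [terminology_store()].
#' @export
load_terminology <- function(path) {
  if (!file.exists(path)) abort(sprintf("terminology file not found: %s", path))
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(
      sprintf("malformed terminology JSON in '%s': %s", path, conditionMessage(e)),
      class = "ebm_parse_error")
  )
  if (!is.list(raw)) abort("terminology JSON must be an array of concept objects",
                           class = "ebm_parse_error")
  rows <- purrr::imap(raw, function(rec, i) {
    if (is.null(rec$id) || is.null(rec$name)) {
      abort(sprintf("terminology record %d lacks 'id' or 'name'", i),
            class = "ebm_parse_error")
    }
    tibble::tibble(
      concept_id = as.character(rec$id),
      preferred_name = as.character(rec$name),
      synonyms = list(as.character(unlist(rec$synonyms %||% list()))),
      semantic_types = list(as.character(unlist(rec$semantic_types %||% list()))),
      entity_type = as.character(rec$entity_type %||% ""),
      parent_ids = list(as.character(unlist(rec$parents %||% list())))
    )
  })
  terminology_store(dplyr::bind_rows(rows))
}

# internal: fetch one concept row by id
.concept_row <- function(store, concept_id) {
  hit <- store$concepts[store$concepts$concept_id == concept_id, ]
  if (nrow(hit) == 0L) {
    abort(sprintf("unknown concept_id: '%s'", concept_id),
          class = "ebm_lookup_error")
  }
  hit
}

#' Parent concepts of a concept
#'
#' Returns the immediate (one-level) parents of a concept, in the order the
#' fixture lists them.
#'
#' @param concept_id Concept identifier present in the store.
#' @param store A [terminology_store()].
#' @return Tibble of parent concepts (possibly zero rows).
#' @export
parent_concepts <- function(concept_id, store) {
  stopifnot(inherits(store, "terminology_store"))
  row <- .concept_row(store, concept_id)
  pids <- row$parent_ids[[1]]
  if (length(pids) == 0L) return(store$concepts[0, ])
  dplyr::bind_rows(lapply(pids, function(p) .concept_row(store, p)))
}

# Partial match predicate: the normalized term's token set is a non-empty
# proper subset of the concept name's token set (or vice versa), sharing at
# least one token of length >= 4.
.partial_match <- function(key_tokens, term_tokens) {
  a <- unique(term_tokens); b <- unique(key_tokens)
  if (length(a) == 0L || length(b) == 0L) return(FALSE)
  shared <- intersect(a, b)
  if (!any(nchar(shared) >= 4L)) return(FALSE)
  proper_subset <- function(x, y) length(x) < length(y) && all(x %in% y)
  proper_subset(a, b) || proper_subset(b, a)
}

#' Match a surface term against the terminology (STI weighting)
#'
#' Weight-based matcher: an exact match on a normalized preferred name gets
#' weight 1.0; a whole-name synonym match or a token-subset partial match
#' gets weight 0.5; otherwise weight 0 and no concept. Precedence is
#' exact > synonym > partial; ties at one level go to the concept with the
#' longest matched name, then the lexicographically smallest `concept_id`.
#' The single best match per term is returned.
#'
#' @param term Character vector of surface terms (each non-empty).
#' @param store A [terminology_store()].
#' @return A tibble with one row per term: `surface_term`, `concept_id`
#'   (NA when unmatched), `match_level` (`exact`, `synonym`, `partial`,
#'   `none`) and `weight` (1.0, 0.5 or 0.0).
#' @export
sti_match <- function(term, store) {
  stopifnot(inherits(store, "terminology_store"))
  if (length(term) == 0L || any(!nzchar(trimws(term)))) {
    abort("sti_match() requires non-empty terms")
  }
  purrr::map_dfr(term, .sti_match_one, store = store)
}

.sti_match_one <- function(term, store) {
  norm <- normalize_term(term)
  idx <- store$index
  no_match <- tibble::tibble(
    surface_term = term, concept_id = NA_character_,
    match_level = "none", weight = 0.0
  )
  if (!nzchar(norm)) return(no_match)

  pick <- function(cands) {
    # longest matched name first, then smallest concept_id
    cands <- cands[order(-cands$key_nchar, cands$concept_id), ]
    cands[1L, ]
  }

  hits <- idx[idx$key == norm, ]
  exact <- hits[hits$kind == "preferred", ]
  if (nrow(exact)) {
    best <- pick(exact)
    return(tibble::tibble(surface_term = term, concept_id = best$concept_id,
                          match_level = "exact", weight = 1.0))
  }
  syn <- hits[hits$kind == "synonym", ]
  if (nrow(syn)) {
    best <- pick(syn)
    return(tibble::tibble(surface_term = term, concept_id = best$concept_id,
                          match_level = "synonym", weight = 0.5))
  }

  term_tokens <- strsplit(norm, " ")[[1]]
  key_tokens <- strsplit(idx$key, " ")
  part <- vapply(key_tokens, .partial_match, logical(1),
                 term_tokens = term_tokens)
  if (any(part)) {
    best <- pick(idx[part, ])
    return(tibble::tibble(surface_term = term, concept_id = best$concept_id,
                          match_level = "partial", weight = 0.5))
  }
  no_match
}
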