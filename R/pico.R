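# Well-built clinical questions in PICO format, built either from free
# clinical text (candidate n-grams matched against the terminology and
# slotted by semantic/entity type) or from decision-support knowledge rules
# (data elements -> P, action elements -> I and C, purpose -> O).

#' Construct a PICO question
#'
#' @param terms Tibble with columns `surface`, `concept_id`, `weight`,
#'   `slot` (one of "P","I","C","O"); zero rows allowed.
#' @param query_type One of "diagnosis", "treatment", "prognosis",
#'   "etiology", "unknown".
#' @return A `pico_question` object. A question is searchable when it has at
#'   least one P or I term (the core of a well-built question).
#' @export
pico_question <- function(terms = NULL, query_type = "unknown") {
  if (is.null(terms)) {
    terms <- tibble::tibble(surface = character(), concept_id = character(),
                            weight = numeric(), slot = character())
  }
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("surface", "concept_id", "weight", "slot") %in% names(terms)))
  if (!all(terms$slot %in% c("P", "I", "C", "O"))) {
    abort("slot must be one of P, I, C, O")
  }
  if (anyDuplicated(terms$surface)) {
    abort("a surface term may appear in at most one PICO slot")
  }
  query_type <- match.arg(query_type, QUERY_TYPES)
  structure(
    list(terms = terms, query_type = query_type),
    class = "pico_question"
  )
}

#' @export
print.pico_question <- function(x, ...) {
  cat(sprintf("<pico_question: type=%s, searchable=%s>\n",
              x$query_type, is_searchable(x)))
  for (s in c("P", "I", "C", "O")) {
    tt <- pico_slot(x, s)
    if (nrow(tt)) {
      cat(sprintf("  %s: %s\n", s,
                  paste(sprintf("%s (w=%.1f)", tt$surface, tt$weight),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' Terms in one PICO slot
#' @param q A `pico_question`.
#' @param slot One of "P","I","C","O".
#' @return Tibble of the slot's weighted terms.
#' @export
pico_slot <- function(q, slot) {
  stopifnot(inherits(q, "pico_question"))
  q$terms[q$terms$slot == slot, , drop = FALSE]
}

#' Is a PICO question searchable?
#'
#' A question is searchable when its P and I slots are not both empty.
#'
#' @param q A `pico_question`.
#' @return Logical scalar.
#' @export
is_searchable <- function(q) {
  stopifnot(inherits(q, "pico_question"))
  any(q$terms$slot %in% c("P", "I"))
}

# ---- configuration tables ---------------------------------------------------

#' Default slot-mapping table
#'
#' Maps semantic types and entity types to PICO slots. Ships as editable
#' JSON under `extdata/config/slot_mapping.json`; population/disorder/finding
#' types map to P, drug and procedure types to I, outcome/qualifier types to
#' O, and anything unlisted falls back to P with a warning.
#'
#' @param path Optional path to an alternative JSON mapping.
#' @return Named list with `semantic_types`, `entity_types`, `fallback`.
#' @export
slot_mapping <- function(path = NULL) {
  path <- path %||% ebm_extdata("config", "slot_mapping.json")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Default query-type translation table
#'
#' Maps parent-concept names and semantic types to a query purpose
#' (diagnosis/treatment/prognosis/etiology); used by [identify_query_type()].
#'
#' @param path Optional path to an alternative JSON table.
#' @return Named list with `concept_names` and `semantic_types` maps.
#' @export
query_type_translation <- function(path = NULL) {
  path <- path %||% ebm_extdata("config", "query_type_translation.json")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# ---- slot assignment --------------------------------------------------------

#' Assign a matched concept to a PICO slot
#'
#' Population, disorder and finding types go to P; drug and procedure types
#' are interventions — the first such concept in a question goes to I and
#' later ones to C (the comparison reading of PICO); outcome-like types go
#' to O. A type not covered by the mapping table falls back to P with a
#' warning rather than dropping a matched concept.
#'
#' @param concept One-row tibble of the concept (as stored in a
#'   [terminology_store()]).
#' @param mapping Slot-mapping table from [slot_mapping()].
#' @param have_intervention Logical; TRUE when the question already has an
#'   I-slot term (later intervention concepts become C).
#' @return A slot letter: "P", "I", "C" or "O".
#' @export
assign_slot <- function(concept, mapping = slot_mapping(),
                        have_intervention = FALSE) {
  stypes <- normalize_term(concept$semantic_types[[1]] %||% character(0))
  etype <- normalize_term(concept$entity_type %||% "")
  slot <- NA_character_
  for (st in stypes) {
    hit <- mapping$semantic_types[[st]]
    if (!is.null(hit)) { slot <- hit; break }
  }
  if (is.na(slot) && nzchar(etype)) {
    hit <- mapping$entity_types[[etype]]
    if (!is.null(hit)) slot <- hit
  }
  if (is.na(slot)) {
    warn(sprintf(
      "concept '%s' has no slot-mapped semantic/entity type; defaulting to P",
      concept$preferred_name))
    slot <- mapping$fallback %||% "P"
  }
  if (slot == "I" && have_intervention) slot <- "C"
  slot
}

# ---- free-text pipeline -----------------------------------------------------

# Candidate phrase scan over the stopword-filtered lowercase token
# sequence: every n-gram (n <= 4) is STI-matched, then candidates are
# accepted greedily — better match level first (exact > synonym > partial),
# longer phrase first, earlier position first — consuming token positions,
# so an exact "blood pressure" beats a partial "raised blood pressure" and
# both beat their unigrams. Accepted matches are returned in text order.
.scan_candidates <- function(tokens, store, max_n = 4L) {
  empty <- tibble::tibble(surface_term = character(), concept_id = character(),
                          match_level = character(), weight = numeric(),
                          position = integer())
  n_tok <- length(tokens)
  if (n_tok == 0L) return(empty)
  cands <- list()
  for (n in seq_len(min(max_n, n_tok))) {
    for (start in seq_len(n_tok - n + 1L)) {
      phrase <- paste(tokens[start:(start + n - 1L)], collapse = " ")
      m <- .sti_match_one(phrase, store)
      if (m$match_level != "none") {
        m$position <- start
        m$ngram <- n
        cands[[length(cands) + 1L]] <- m
      }
    }
  }
  if (!length(cands)) return(empty)
  cands <- dplyr::bind_rows(cands)
  level_rank <- match(cands$match_level, c("exact", "synonym", "partial"))
  cands <- cands[order(level_rank, -cands$ngram, cands$position), ,
                 drop = FALSE]
  consumed <- logical(n_tok)
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    idx <- cands$position[i]:(cands$position[i] + cands$ngram[i] - 1L)
    if (!any(consumed[idx])) {
      consumed[idx] <- TRUE
      keep[i] <- TRUE
    }
  }
  res <- cands[keep, , drop = FALSE]
  res <- res[order(res$position), , drop = FALSE]
  res$ngram <- NULL
  # one appearance per concept: keep the first
  res[!duplicated(res$concept_id), , drop = FALSE]
}

#' Build a PICO question from free clinical text
#'
#' Pipeline: whitespace tokenization, stopword removal and case folding
#' (Porter stemming is applied only for duplicate-candidate collapsing, not
#' for vocabulary lookup); candidate n-grams (n <= 4) are matched against
#' the terminology with [sti_match()]; matched concepts are slotted with
#' [assign_slot()] in text order; the query type is inferred with
#' [identify_query_type()].
#'
#' If no concept matches, an empty, unsearchable question is returned (not
#' an error).
#'
#' @param text Clinical scenario text (non-empty string).
#' @param store A [terminology_store()].
#' @param mapping Slot-mapping table, default [slot_mapping()].
#' @param translation Query-type translation table, default
#'   [query_type_translation()].
#' @return A [pico_question()].
#' @export
pico_from_text <- function(text, store, mapping = slot_mapping(),
                           translation = query_type_translation()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) abort("text must be non-empty")
  stopifnot(inherits(store, "terminology_store"))

  tokens <- normalize_term(tokenize_ws(text))
  tokens <- unlist(strsplit(tokens, " "), use.names = FALSE)
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!(tokens %in% ebm_stopwords())]
  if (!length(tokens)) return(pico_question())

  cands <- .scan_candidates(tokens, store)
  # collapse candidates whose stemmed surface duplicates an earlier one
  if (nrow(cands) > 1L) {
    stems <- vapply(strsplit(cands$surface_term, " "), function(tk)
      paste(porter_stem(tk), collapse = " "), character(1))
    cands <- cands[!duplicated(stems), , drop = FALSE]
  }
  if (nrow(cands) == 0L) return(pico_question())

  slots <- character(nrow(cands))
  have_i <- FALSE
  for (i in seq_len(nrow(cands))) {
    con <- .concept_row(store, cands$concept_id[i])
    slots[i] <- assign_slot(con, mapping, have_intervention = have_i)
    if (slots[i] == "I") have_i <- TRUE
  }
  terms <- tibble::tibble(
    surface = cands$surface_term,
    concept_id = cands$concept_id,
    weight = cands$weight,
    slot = slots
  )
  q <- pico_question(terms)
  q$query_type <- identify_query_type(q, store, translation)
  q
}

# ---- rule input -------------------------------------------------------------

#' Construct a decision-support knowledge rule
#'
#' Rule elements arrive pre-extracted: `data_elements` (the rule's data
#' part), `action_elements` (its action part) and an optional `purpose`.
#'
#' @param data_elements Character vector, non-empty.
#' @param action_elements Character vector.
#' @param purpose Optional string.
#' @param scheme "production_rule" or "mlm".
#' @return A `knowledge_rule` object.
#' @export
knowledge_rule <- function(data_elements, action_elements = character(0),
                           purpose = NULL,
                           scheme = c("production_rule", "mlm")) {
  scheme <- match.arg(scheme)
  data_elements <- as.character(data_elements)
  if (length(data_elements) == 0L || all(!nzchar(data_elements))) {
    abort("a knowledge rule needs at least one data element",
          class = "ebm_validation_error")
  }
  structure(
    list(data_elements = data_elements,
         action_elements = as.character(action_elements),
         purpose = purpose, scheme = scheme),
    class = "knowledge_rule"
  )
}

#' Read a knowledge rule from JSON
#'
#' Schema: `{"scheme": "production_rule"|"mlm", "data": [...],
#' "action": [...], "purpose": "..."}`.
#'
#' @param path Path to the rule JSON file.
#' @return A [knowledge_rule()].
#' @export
read_rule <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  knowledge_rule(
    data_elements = raw$data,
    action_elements = raw$action %||% character(0),
    purpose = raw$purpose,
    scheme = raw$scheme %||% "production_rule"
  )
}

#' Build a PICO question from a knowledge rule
#'
#' Rule-to-PICO mapping: data elements map to P, action elements map to the
#' intervention side (the first action element to I, the rest to C), and the
#' rule's purpose, when present, maps to O. A production rule without a
#' purpose leaves O unmapped. Elements are standardized against the
#' terminology when a store is supplied; unmatched elements are kept with
#' weight 0 so the rule's content is never dropped.
#'
#' @param rule A [knowledge_rule()].
#' @param store Optional [terminology_store()] used for standardization and
#'   query-type inference.
#' @param translation Query-type translation table.
#' @return A [pico_question()].
#' @export
pico_from_rule <- function(rule, store = NULL,
                           translation = query_type_translation()) {
  stopifnot(inherits(rule, "knowledge_rule"))
  surfaces <- c(rule$data_elements, rule$action_elements,
                if (!is.null(rule$purpose)) rule$purpose)
  slots <- c(rep("P", length(rule$data_elements)),
             if (length(rule$action_elements))
               c("I", rep("C", length(rule$action_elements) - 1L)),
             if (!is.null(rule$purpose)) "O")
  # order-insensitive over data elements: sort P surfaces
  ord <- order(slots != "P", ifelse(slots == "P", surfaces, ""))
  surfaces <- surfaces[ord]; slots <- slots[ord]

  if (!is.null(store)) {
    m <- sti_match(surfaces, store)
    concept_id <- m$concept_id
    weight <- m$weight
  } else {
    concept_id <- rep(NA_character_, length(surfaces))
    weight <- rep(0, length(surfaces))
  }
  terms <- tibble::tibble(surface = surfaces, concept_id = concept_id,
                          weight = weight, slot = slots)
  terms <- terms[!duplicated(terms$surface), , drop = FALSE]
  q <- pico_question(terms)
  if (!is.null(store)) q$query_type <- identify_query_type(q, store, translation)
  q
}

#' Build a PICO question from a structured, pre-labeled record
#'
#' Structured input arrives with fields already labeled `problem`,
#' `intervention`, `comparison`, `outcome` (each a character vector); terms
#' pass through [sti_match()] only for standardization and weighting.
#'
#' @param record Named list (or parsed JSON) with any of the four fields.
#' @param store Optional [terminology_store()].
#' @param translation Query-type translation table.
#' @return A [pico_question()].
#' @export
pico_from_record <- function(record, store = NULL,
                             translation = query_type_translation()) {
  fields <- list(P = "problem", I = "intervention", C = "comparison",
                 O = "outcome")
  surfaces <- character(0); slots <- character(0)
  for (s in names(fields)) {
    vals <- as.character(record[[fields[[s]]]] %||% character(0))
    surfaces <- c(surfaces, vals)
    slots <- c(slots, rep(s, length(vals)))
  }
  if (!length(surfaces)) return(pico_question())
  if (!is.null(store)) {
    m <- sti_match(surfaces, store)
    concept_id <- m$concept_id; weight <- m$weight
  } else {
    concept_id <- rep(NA_character_, length(surfaces))
    weight <- rep(0, length(surfaces))
  }
  terms <- tibble::tibble(surface = surfaces, concept_id = concept_id,
                          weight = weight, slot = slots)
  terms <- terms[!duplicated(terms$surface), , drop = FALSE]
  q <- pico_question(terms)
  if (!is.null(store)) q$query_type <- identify_query_type(q, store, translation)
  q
}

# ---- query-type inference ---------------------------------------------------

#' Infer the purpose (query type) of a PICO question
#'
#' Collects the parent concepts of every I and C concept, translates each
#' parent through the translation table (by normalized concept name, falling
#' back to the parent's semantic types), and returns the majority vote.
#' Ties are broken by the fixed priority treatment > diagnosis > prognosis >
#' etiology. An empty I/C set, or no translatable parent, yields "unknown".
#'
#' @param q A [pico_question()].
#' @param store A [terminology_store()].
#' @param translation Table from [query_type_translation()].
#' @return One of "diagnosis", "treatment", "prognosis", "etiology",
#'   "unknown".
#' @export
identify_query_type <- function(q, store,
                                translation = query_type_translation()) {
  stopifnot(inherits(q, "pico_question"), inherits(store, "terminology_store"))
  ic <- q$terms[q$terms$slot %in% c("I", "C") & !is.na(q$terms$concept_id), ]
  if (nrow(ic) == 0L) return("unknown")
  votes <- character(0)
  for (cid in ic$concept_id) {
    parents <- parent_concepts(cid, store)
    if (nrow(parents) == 0L) next
    for (j in seq_len(nrow(parents))) {
      nm <- normalize_term(parents$preferred_name[j])
      tr <- translation$concept_names[[nm]]
      if (is.null(tr)) {
        for (st in normalize_term(parents$semantic_types[[j]])) {
          tr <- translation$semantic_types[[st]]
          if (!is.null(tr)) break
        }
      }
      if (!is.null(tr)) votes <- c(votes, tr)
    }
  }
  if (length(votes) == 0L) return("unknown")
  counts <- table(votes)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  QUERY_TYPE_PRIORITY[QUERY_TYPE_PRIORITY %in% top][1]
}
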