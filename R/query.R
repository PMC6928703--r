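# Boolean query construction, rendering and the retrieval-driven
# optimization loop. A query is a conjunction of groups; each group is a
# disjunction of weighted terms. P and O terms form singleton groups; the I
# and C terms share one OR-group. When too few results come back, terms are
# dropped one at a time: C terms first, then O terms, then the
# lowest-weight remaining P/I term — the P and I core is protected until
# nothing else is left, and the last remaining term is never removed.

#' Construct a boolean query
#'
#' @param groups List of tibbles; each tibble is one OR-group with columns
#'   `surface`, `weight`, `slot`.
#' @param clinical_filter Optional query-type tag ("treatment", ...) used by
#'   the pubmed rendering dialect.
#' @return A `boolean_query` object.
#' @export
boolean_query <- function(groups, clinical_filter = NULL) {
  stopifnot(is.list(groups))
  groups <- purrr::map(groups, tibble::as_tibble)
  sizes <- vapply(groups, nrow, integer(1))
  groups <- groups[sizes > 0L]
  if (length(groups) == 0L) {
    abort("a boolean query needs at least one non-empty group",
          class = "ebm_validation_error")
  }
  structure(
    list(groups = groups, clinical_filter = clinical_filter),
    class = "boolean_query"
  )
}

#' @export
print.boolean_query <- function(x, ...) {
  cat("<boolean_query> ", render_query(x), "\n", sep = "")
  invisible(x)
}

# flat view of all terms with their group index
.query_terms <- function(query) {
  purrr::imap_dfr(query$groups, function(g, i) {
    g$group <- i
    g
  })
}

#' Number of terms in a boolean query
#' @param x A `boolean_query`.
#' @export
length.boolean_query <- function(x) nrow(.query_terms(x))

#' Build a boolean query from a PICO question
#'
#' Each P term becomes its own AND-group; all I and C terms (I first, in
#' question order) form a single OR-group; each O term is an AND-group
#' appended last. The inferred query type, when known, is attached as the
#' clinical filter.
#'
#' @param q A searchable [pico_question()].
#' @return A [boolean_query()].
#' @export
build_query <- function(q) {
  stopifnot(inherits(q, "pico_question"))
  if (!is_searchable(q)) {
    abort("question has no P or I terms; not searchable",
          class = "ebm_validation_error")
  }
  cols <- c("surface", "weight", "slot")
  groups <- list()
  p <- pico_slot(q, "P")
  for (i in seq_len(nrow(p))) groups <- c(groups, list(p[i, cols]))
  ic <- dplyr::bind_rows(pico_slot(q, "I"), pico_slot(q, "C"))
  if (nrow(ic)) groups <- c(groups, list(ic[, cols]))
  o <- pico_slot(q, "O")
  for (i in seq_len(nrow(o))) groups <- c(groups, list(o[i, cols]))
  filter <- if (q$query_type != "unknown") q$query_type else NULL
  boolean_query(groups, clinical_filter = filter)
}

#' Packaged clinical-queries filter strings
#'
#' One broad-scope PubMed clinical-queries filter clause per query type;
#' editable JSON under `extdata/config/clinical_filters.json`.
#'
#' @param path Optional alternative JSON file.
#' @return Named list of filter clauses.
#' @export
clinical_filters <- function(path = NULL) {
  path <- path %||% ebm_extdata("config", "clinical_filters.json")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Render a boolean query as a search string
#'
#' The plain dialect joins AND-groups with `AND` and parenthesizes
#' multi-term OR-groups; the pubmed dialect additionally appends the
#' clinical-queries filter clause for the query's clinical filter tag.
#'
#' @param query A [boolean_query()].
#' @param dialect "plain" or "pubmed".
#' @param filters Filter table from [clinical_filters()] (pubmed dialect).
#' @return A single query string.
#' @export
render_query <- function(query, dialect = c("plain", "pubmed"),
                         filters = clinical_filters()) {
  stopifnot(inherits(query, "boolean_query"))
  dialect <- match.arg(dialect)
  parts <- vapply(query$groups, function(g) {
    if (nrow(g) == 1L) g$surface else
      paste0("(", paste(g$surface, collapse = " OR "), ")")
  }, character(1))
  out <- paste(parts, collapse = " AND ")
  if (dialect == "pubmed" && !is.null(query$clinical_filter)) {
    clause <- filters[[query$clinical_filter]]
    if (!is.null(clause)) out <- paste(out, "AND", clause)
  }
  out
}

#' Compare two query strings modulo the implicit-AND convention
#'
#' PubMed treats adjacency as conjunction and intra-word punctuation as a
#' word separator, so `female blood pressure AND (beta-blocker OR x)` and
#' `female AND blood pressure AND (beta blocker OR x)` denote the same
#' query. This helper lowercases, strips punctuation other than
#' parentheses, drops explicit AND tokens and collapses whitespace before
#' comparing.
#'
#' @param a,b Query strings.
#' @return Logical scalar.
#' @export
query_strings_equivalent <- function(a, b) {
  canon <- function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9()]+", " ", x)
    x <- gsub("\\band\\b", " ", x)
    x <- gsub("\\s*\\(\\s*", " ( ", x)
    x <- gsub("\\s*\\)\\s*", " ) ", x)
    trimws(gsub("\\s+", " ", x))
  }
  identical(canon(a), canon(b))
}

# Remove one term from the query following the optimization order:
# first a C term, then an O term, then the lowest-weight P/I term.
# Within a slot class the lowest weight goes first; ties drop the most
# recently added (right-most) term. Returns NULL when only one term remains.
.drop_one_term <- function(query) {
  terms <- .query_terms(query)
  terms$pos <- seq_len(nrow(terms))
  if (nrow(terms) <= 1L) return(NULL)
  candidate <- NULL
  for (cls in list("C", "O", c("P", "I"))) {
    pool <- terms[terms$slot %in% cls, , drop = FALSE]
    if (nrow(pool)) {
      pool <- pool[pool$weight == min(pool$weight), , drop = FALSE]
      candidate <- pool[which.max(pool$pos), ]
      break
    }
  }
  if (is.null(candidate)) return(NULL)
  groups <- query$groups
  g <- candidate$group
  keep <- groups[[g]]$surface != candidate$surface
  groups[[g]] <- groups[[g]][keep, , drop = FALSE]
  groups <- groups[vapply(groups, nrow, integer(1)) > 0L]
  new_q <- boolean_query(groups, clinical_filter = query$clinical_filter)
  list(query = new_q, removed = candidate)
}

#' Optimize a boolean query against a search backend
#'
#' Runs the query; while the hit count is below `min_results` and more than
#' one term remains, removes one term per iteration — C terms first, then O
#' terms, then the lowest-STI-weight P/I term — and re-runs the search.
#' Returns the final query, its outcome and the removal log. If even the
#' single-term query returns nothing the (empty) outcome is returned with
#' `satisfied = FALSE`.
#'
#' @param query A [boolean_query()].
#' @param backend A search backend (see [fixture_backend()]).
#' @param min_results Minimum acceptable number of hits (default 1).
#' @param max_results Optional ceiling; exceeding it only raises a warning.
#' @return List with elements `query`, `outcome`, `removed` (tibble of
#'   dropped terms in removal order) and `satisfied`.
#' @export
optimize_query <- function(query, backend, min_results = 1L,
                           max_results = NULL) {
  stopifnot(inherits(query, "boolean_query"), min_results >= 1L)
  removed <- list()
  repeat {
    outcome <- backend_search(backend, query)
    if (outcome$total_count >= min_results) {
      if (!is.null(max_results) && outcome$total_count > max_results) {
        warn(sprintf("query returns %d results (> max_results = %d)",
                     outcome$total_count, max_results))
      }
      return(list(query = query, outcome = outcome,
                  removed = dplyr::bind_rows(removed), satisfied = TRUE))
    }
    step <- .drop_one_term(query)
    if (is.null(step)) {
      return(list(query = query, outcome = outcome,
                  removed = dplyr::bind_rows(removed), satisfied = FALSE))
    }
    removed <- c(removed, list(step$removed))
    query <- step$query
  }
}
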