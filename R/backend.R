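# Search backend contract: search(boolean_query) -> search_outcome and
# fetch(ids) -> article tibble. The fixture backend evaluates queries
# against token indexes of packaged records and is fully deterministic; the
# live backend drives NCBI eUtils (ePost/eSearch/eFetch with the history
# server) and needs network access.

#' Construct a search outcome
#'
#' @param article_ids Character vector of article identifiers.
#' @param total_count Total number of matches (>= length(article_ids)).
#' @return A `search_outcome` object.
#' @export
search_outcome <- function(article_ids, total_count = length(article_ids)) {
  article_ids <- as.character(article_ids)
  total_count <- as.integer(total_count)
  stopifnot(total_count >= length(article_ids))
  structure(list(article_ids = article_ids, total_count = total_count),
            class = "search_outcome")
}

#' @export
print.search_outcome <- function(x, ...) {
  cat(sprintf("<search_outcome: %d hits>\n", x$total_count))
  invisible(x)
}

#' Run a query through a backend
#' @param backend A search backend object.
#' @param query A [boolean_query()].
#' @return A [search_outcome()].
#' @export
backend_search <- function(backend, query) UseMethod("backend_search")

#' Fetch article records from a backend
#' @param backend A search backend object.
#' @param ids Character vector of article identifiers.
#' @return Tibble of article records.
#' @export
backend_fetch <- function(backend, ids) UseMethod("backend_fetch")

# ---- fixture backend --------------------------------------------------------

#' Offline search backend over in-memory article records
#'
#' Evaluates boolean queries against the normalized text of each record's
#' title, abstract and MeSH terms: a term hits when it occurs as a
#' contiguous word sequence; groups are ORed internally and ANDed together.
#' Fully deterministic — hits are returned in record order.
#'
#' @param records Article tibble as returned by [parse_medline_xml()].
#' @return A `fixture_backend` object implementing the backend contract.
#' @export
fixture_backend <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(nrow(records) >= 1L, "article_id" %in% names(records))
  texts <- vapply(seq_len(nrow(records)), function(i) {
    normalize_term(paste(
      records$title[i], records$abstract[i],
      paste(records$mesh_terms[[i]], collapse = " ")
    ))
  }, character(1))
  structure(list(records = records, texts = texts),
            class = c("fixture_backend", "search_backend"))
}

# phrase occurrence as whole-word sequence in pre-normalized text
.phrase_hit <- function(texts, term) {
  pat <- paste0("\\b", gsub(" ", "\\\\s+", normalize_term(term)), "\\b")
  grepl(pat, texts, perl = TRUE)
}

#' @export
backend_search.fixture_backend <- function(backend, query) {
  stopifnot(inherits(query, "boolean_query"))
  hit <- rep(TRUE, length(backend$texts))
  for (g in query$groups) {
    ghit <- rep(FALSE, length(backend$texts))
    for (term in g$surface) ghit <- ghit | .phrase_hit(backend$texts, term)
    hit <- hit & ghit
  }
  ids <- backend$records$article_id[hit]
  search_outcome(ids, sum(hit))
}

#' @export
backend_fetch.fixture_backend <- function(backend, ids) {
  recs <- backend$records
  recs[match(ids, recs$article_id), , drop = FALSE]
}

# ---- live NCBI eUtils backend ----------------------------------------------

#' Live PubMed backend via NCBI eUtils
#'
#' Thin client for eSearch/eFetch with the history server enabled
#' (`usehistory=y`). Requires network access; intended for interactive use,
#' never exercised by the test suite. Respects an optional API key and a
#' minimum delay between requests.
#'
#' @param api_key Optional NCBI API key.
#' @param delay Seconds to sleep before each request (rate limiting).
#' @param retmax Maximum number of ids to retrieve per search.
#' @return An `entrez_backend` object implementing the backend contract.
#' @export
entrez_backend <- function(api_key = NULL, delay = 0.4, retmax = 100L) {
  structure(list(api_key = api_key, delay = delay, retmax = as.integer(retmax),
                 base = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"),
            class = c("entrez_backend", "search_backend"))
}

.entrez_url <- function(backend, endpoint, params) {
  if (!is.null(backend$api_key)) params$api_key <- backend$api_key
  qs <- paste(names(params), vapply(params, utils::URLencode, character(1),
                                    reserved = TRUE), sep = "=", collapse = "&")
  sprintf("%s/%s?%s", backend$base, endpoint, qs)
}

#' @export
backend_search.entrez_backend <- function(backend, query) {
  Sys.sleep(backend$delay)
  term <- render_query(query, dialect = "pubmed")
  url <- .entrez_url(backend, "esearch.fcgi", list(
    db = "pubmed", term = term, retmax = backend$retmax,
    usehistory = "y", retmode = "json"))
  res <- tryCatch(jsonlite::fromJSON(url), error = function(e) {
    abort(sprintf("eSearch request failed for query '%s': %s",
                  term, conditionMessage(e)),
          class = "ebm_transport_error")
  })
  search_outcome(res$esearchresult$idlist %||% character(0),
                 as.integer(res$esearchresult$count %||% 0))
}

#' @export
backend_fetch.entrez_backend <- function(backend, ids) {
  if (!length(ids)) return(parse_medline_xml(xml2::read_xml(
    "<PubmedArticleSet/>")))
  Sys.sleep(backend$delay)
  url <- .entrez_url(backend, "efetch.fcgi", list(
    db = "pubmed", id = paste(ids, collapse = ","), retmode = "xml"))
  doc <- tryCatch(xml2::read_xml(url), error = function(e) {
    abort(sprintf("eFetch request failed: %s", conditionMessage(e)),
          class = "ebm_transport_error")
  })
  parse_medline_xml(doc)
}
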