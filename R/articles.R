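# MEDLINE/PubMed record handling and the two-block feature representation:
# data features (title + abstract, lowercased, stopword-filtered,
# Porter-stemmed, length-filtered) and metadata features (MeSH terms and
# publication types, tokenized and case-folded only, kept in a disjoint
# "meta:" namespace).

META_PREFIX <- "meta:"

#' Parse PubMed eFetch XML into an article tibble
#'
#' One row per `PubmedArticle`; a missing abstract becomes the empty string,
#' and all MeSH descriptor names and publication types are captured.
#' Records without a PMID are skipped with a warning.
#'
#' @param xml Path to an XML file, an XML string, or an `xml_document`.
#' @return Tibble with columns `article_id`, `title`, `abstract`,
#'   `mesh_terms` (list), `publication_types` (list), `journal`, `year`.
#' @export
parse_medline_xml <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else {
    tryCatch(xml2::read_xml(xml), error = function(e) {
      abort(sprintf("malformed MEDLINE XML: %s", conditionMessage(e)),
            class = "ebm_parse_error")
    })
  }
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  empty <- tibble::tibble(
    article_id = character(), title = character(), abstract = character(),
    mesh_terms = list(), publication_types = list(),
    journal = character(), year = integer()
  )
  if (length(arts) == 0L) return(empty)

  skipped <- 0L
  rows <- lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abs_nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abstract <- if (length(abs_nodes)) {
      paste(xml2::xml_text(abs_nodes), collapse = " ")
    } else ""
    mesh <- xml2::xml_text(
      xml2::xml_find_all(a, ".//MeshHeading/DescriptorName"))
    ptypes <- xml2::xml_text(xml2::xml_find_all(a, ".//PublicationType"))
    journal <- xml2::xml_text(xml2::xml_find_first(a, ".//Journal/Title"))
    year <- xml2::xml_text(xml2::xml_find_first(
      a, ".//JournalIssue/PubDate/Year"))
    year <- suppressWarnings(as.integer(year))
    if (!is.na(year) && (year < 1800L || year > 2100L)) {
      abort(sprintf("implausible publication year %d for PMID %s", year, pmid))
    }
    tibble::tibble(
      article_id = pmid,
      title = ifelse(is.na(title), "", title),
      abstract = abstract,
      mesh_terms = list(mesh),
      publication_types = list(ptypes),
      journal = ifelse(is.na(journal), "", journal),
      year = year
    )
  })
  if (skipped > 0L) {
    warn(sprintf("skipped %d record(s) without a PMID", skipped))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty else out
}

#' Serialize article records to MEDLINE-style XML
#'
#' Writes the minimal PubMed eFetch structure that [parse_medline_xml()]
#' reads back unchanged (round trip).
#'
#' @param records Article tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(records, path) {
  records <- tibble::as_tibble(records)
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(records))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", records$article_id[i])
    a <- xml2::xml_add_child(cit, "Article")
    j <- xml2::xml_add_child(a, "Journal")
    ji <- xml2::xml_add_child(j, "JournalIssue")
    pd <- xml2::xml_add_child(ji, "PubDate")
    if (!is.na(records$year[i])) {
      xml2::xml_add_child(pd, "Year", as.character(records$year[i]))
    }
    xml2::xml_add_child(j, "Title", records$journal[i])
    xml2::xml_add_child(a, "ArticleTitle", records$title[i])
    if (nzchar(records$abstract[i])) {
      abs <- xml2::xml_add_child(a, "Abstract")
      xml2::xml_add_child(abs, "AbstractText", records$abstract[i])
    }
    ptl <- xml2::xml_add_child(a, "PublicationTypeList")
    for (pt in records$publication_types[[i]]) {
      xml2::xml_add_child(ptl, "PublicationType", pt)
    }
    if (length(records$mesh_terms[[i]])) {
      mhl <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (mt in records$mesh_terms[[i]]) {
        mh <- xml2::xml_add_child(mhl, "MeshHeading")
        xml2::xml_add_child(mh, "DescriptorName", mt)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- corpus JSONL -----------------------------------------------------------

#' Write a corpus as JSONL
#'
#' One JSON object per line mirroring the article tibble columns, plus an
#' optional `label` column ("rigor"/"nonrigor").
#'
#' @param records Article tibble (optionally with a `label` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(records, path) {
  records <- tibble::as_tibble(records)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    obj <- list(
      article_id = records$article_id[i],
      title = records$title[i],
      abstract = records$abstract[i],
      mesh_terms = records$mesh_terms[[i]],
      publication_types = records$publication_types[[i]],
      journal = records$journal[i],
      year = records$year[i]
    )
    if ("label" %in% names(records)) obj$label <- records$label[i]
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}

#' Read a JSONL corpus
#'
#' @param path Path written by [write_corpus_jsonl()].
#' @return Article tibble (with `label` when present).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    tibble::tibble(
      article_id = o$article_id, title = o$title %||% "",
      abstract = o$abstract %||% "",
      mesh_terms = list(as.character(o$mesh_terms %||% character(0))),
      publication_types = list(as.character(o$publication_types %||%
                                              character(0))),
      journal = o$journal %||% "", year = as.integer(o$year %||% NA),
      label = o$label %||% NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$label))) out$label <- NULL
  out
}

# ---- feature maps -----------------------------------------------------------

#' Data-feature token map of one article
#'
#' Tokens from the concatenated title and abstract, lowercased,
#' stopword-filtered, Porter-stemmed and length-filtered.
#'
#' @param title,abstract Strings (abstract may be empty).
#' @param min_len,max_len Token length bounds (defaults 2 and 25).
#' @return Named integer vector of token counts.
#' @export
data_features <- function(title, abstract = "", min_len = 2L, max_len = 25L) {
  toks <- feature_tokens(paste(title, abstract), min_len, max_len)
  if (!length(toks)) return(setNames(integer(0), character(0)))
  tab <- table(toks)
  setNames(as.integer(tab), names(tab))
}

#' Metadata-feature token map of one article
#'
#' MeSH terms and publication types, tokenized and lowercased only — no
#' stopword removal and no stemming — prefixed with `meta:` so the metadata
#' namespace stays disjoint from the data features. Tokens are counted per
#' occurrence.
#'
#' @param mesh_terms,publication_types Character vectors.
#' @return Named integer vector of prefixed token counts.
#' @export
metadata_features <- function(mesh_terms = character(0),
                              publication_types = character(0)) {
  toks <- meta_tokens(c(mesh_terms, publication_types))
  if (!length(toks)) return(setNames(integer(0), character(0)))
  tab <- table(paste0(META_PREFIX, toks))
  setNames(as.integer(tab), names(tab))
}

#' Vectorize a corpus into a sparse feature matrix
#'
#' Builds the union vocabulary of data and metadata tokens over all records
#' and returns a sparse document-by-term matrix. The default weighting is
#' smoothed TF-IDF (idf = log((1+n)/(1+df)) + 1) with L2 row normalization;
#' raw counts and binary indicators are available for ablation. When a
#' `vocabulary` (with its IDF weights) is supplied, the corpus is projected
#' onto it — this is how a trained model scores new articles.
#'
#' @param records Article tibble (>= 1 row).
#' @param scheme "tfidf", "count" or "binary".
#' @param min_len,max_len Data-token length bounds.
#' @param vocabulary Optional vocabulary tibble from a previous call.
#' @return List of class `corpus_features`: `matrix` (dgCMatrix, rows in
#'   record order), `vocabulary` (tibble with `token`, `df`, `idf`), and
#'   `scheme`.
#' @export
vectorize_corpus <- function(records, scheme = c("tfidf", "count", "binary"),
                             min_len = 2L, max_len = 25L, vocabulary = NULL) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    abort("cannot vectorize an empty corpus", class = "ebm_validation_error")
  }
  scheme <- match.arg(scheme)
  maps <- lapply(seq_len(nrow(records)), function(i) {
    c(data_features(records$title[i], records$abstract[i], min_len, max_len),
      metadata_features(records$mesh_terms[[i]],
                        records$publication_types[[i]]))
  })
  n <- length(maps)
  if (is.null(vocabulary)) {
    vocab_tokens <- sort(unique(unlist(lapply(maps, names))))
    df <- integer(length(vocab_tokens))
    names(df) <- vocab_tokens
    for (m in maps) df[unique(names(m))] <- df[unique(names(m))] + 1L
    idf <- log((1 + n) / (1 + df)) + 1
    vocabulary <- tibble::tibble(token = vocab_tokens, df = as.integer(df),
                                 idf = as.numeric(idf))
  }
  tok_index <- setNames(seq_len(nrow(vocabulary)), vocabulary$token)

  trips <- lapply(seq_len(n), function(i) {
    m <- maps[[i]]
    m <- m[names(m) %in% names(tok_index)]
    if (!length(m)) return(NULL)
    list(i = rep(i, length(m)), j = unname(tok_index[names(m)]),
         x = as.numeric(m))
  })
  trips <- trips[!vapply(trips, is.null, logical(1))]
  ii <- unlist(lapply(trips, `[[`, "i"), use.names = FALSE)
  jj <- unlist(lapply(trips, `[[`, "j"), use.names = FALSE)
  xx <- unlist(lapply(trips, `[[`, "x"), use.names = FALSE)
  if (is.null(ii)) { ii <- integer(0); jj <- integer(0); xx <- numeric(0) }
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n, nrow(vocabulary)),
                              dimnames = list(records$article_id,
                                              vocabulary$token))
  if (scheme == "binary") {
    mat@x <- rep(1, length(mat@x))
  } else if (scheme == "tfidf") {
    mat <- mat %*% Matrix::Diagonal(x = vocabulary$idf)
    norms <- sqrt(Matrix::rowSums(mat^2))
    norms[norms == 0] <- 1
    mat <- Matrix::Diagonal(x = 1 / norms) %*% mat
    dimnames(mat) <- list(records$article_id, vocabulary$token)
  }
  structure(list(matrix = methods::as(mat, "CsparseMatrix"),
                 vocabulary = vocabulary, scheme = scheme),
            class = "corpus_features")
}

#' @export
print.corpus_features <- function(x, ...) {
  cat(sprintf("<corpus_features: %d articles x %d tokens (%s)>\n",
              nrow(x$matrix), ncol(x$matrix), x$scheme))
  invisible(x)
}
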