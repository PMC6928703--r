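# End-to-end orchestration: input (free text or knowledge rule) -> PICO ->
# boolean query -> search/fetch -> rigor classification -> contextual
# ranking -> summarization -> JSON report. Every stage is also exposed on
# its own; run_pipeline() is their composition, and a fixed seed plus a
# fixed configuration make the report byte-identical across runs.

#' Pipeline configuration
#'
#' @param terminology A [terminology_store()] or a path to terminology JSON.
#' @param backend A search backend object, or "fixture" to build one from
#'   `records`.
#' @param records Article tibble or path to MEDLINE XML (fixture backend).
#' @param model An `eqrm_bundle`, a path to a saved bundle, or NULL to skip
#'   classification.
#' @param min_results Retrieval threshold for [optimize_query()].
#' @param top_k Sentences per PICO element in summaries.
#' @param group_threshold Evidence-grouping similarity threshold.
#' @param user_context Named grades for [rank_articles()].
#' @param seed Integer seed recorded in (and controlling) every report.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(terminology, backend = "fixture", records = NULL,
                            model = NULL, min_results = 1L, top_k = 3L,
                            group_threshold = 0.5,
                            user_context = c(context = "H"), seed = 1L) {
  store <- if (inherits(terminology, "terminology_store")) terminology
           else load_terminology(terminology)
  if (identical(backend, "fixture")) {
    if (is.null(records)) {
      abort("fixture backend needs `records` (tibble or MEDLINE XML path)")
    }
    recs <- if (is.character(records)) parse_medline_xml(records)
            else tibble::as_tibble(records)
    backend <- fixture_backend(recs)
  }
  bundle <- if (is.character(model)) eqrm_load(model) else model
  structure(list(store = store, backend = backend, model = bundle,
                 min_results = as.integer(min_results),
                 top_k = as.integer(top_k),
                 group_threshold = group_threshold,
                 user_context = user_context, seed = as.integer(seed)),
            class = "pipeline_config")
}

.pico_from_input <- function(input, config) {
  if (is.character(input) && length(input) == 1L) {
    input <- list(text = input)
  }
  if (!is.null(input$text)) {
    pico_from_text(input$text, config$store)
  } else if (!is.null(input$rule)) {
    rule <- if (inherits(input$rule, "knowledge_rule")) input$rule
            else read_rule(input$rule)
    pico_from_rule(rule, store = config$store)
  } else {
    abort("input must carry $text or $rule")
  }
}

#' Run the full curation pipeline
#'
#' Builds the PICO question, renders and optimizes the boolean query,
#' fetches the matching articles, scores them for rigor (when a classifier
#' bundle is configured), ranks them under the user context, summarizes
#' primary studies and groups the summaries into evidence. An unsearchable
#' question (no P or I term) raises a condition of class
#' `ebm_unsearchable` naming the empty slots.
#'
#' @param input Scenario text (string or `list(text = ...)`) or a knowledge
#'   rule (`list(rule = ...)`, object or JSON path).
#' @param config A [pipeline_config()].
#' @param output Path for the JSON report, or NULL to skip writing.
#' @return The report as a named list, invisibly when `output` is given.
#' @export
run_pipeline <- function(input, config, output = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  q <- .pico_from_input(input, config)
  if (!is_searchable(q)) {
    empty_slots <- setdiff(c("P", "I"), unique(q$terms$slot))
    abort(sprintf("question is not searchable: slot(s) %s empty",
                  paste(empty_slots, collapse = ", ")),
          class = "ebm_unsearchable")
  }
  query <- build_query(q)
  opt <- optimize_query(query, config$backend,
                        min_results = config$min_results)
  fetched <- backend_fetch(config$backend, opt$outcome$article_ids)

  if (!is.null(config$model) && nrow(fetched)) {
    fetched <- eqrm_classify(config$model, fetched)
  } else if (nrow(fetched)) {
    fetched$rigor_prob <- NA_real_
    fetched$rigor_class <- NA_character_
  }
  ranked <- rank_articles(fetched, user_context = config$user_context)

  summaries <- lapply(seq_len(nrow(ranked)), function(i) {
    summarize_article(ranked[i, ], config$store, top_k = config$top_k)
  })
  groups <- group_evidence(summaries, threshold = config$group_threshold)

  report <- list(
    seed = config$seed,
    config_hash = rlang::hash(list(config$min_results, config$top_k,
                                   config$group_threshold,
                                   config$user_context, config$seed)),
    pico = list(
      terms = as.list(q$terms),
      query_type = q$query_type
    ),
    query = render_query(opt$query),
    query_pubmed = render_query(opt$query, dialect = "pubmed"),
    removed_terms = if (nrow(opt$removed)) opt$removed$surface else character(0),
    retrieval = list(total_count = opt$outcome$total_count,
                     satisfied = opt$satisfied),
    articles = lapply(seq_len(nrow(ranked)), function(i) {
      list(article_id = ranked$article_id[i],
           title = ranked$title[i],
           year = ranked$year[i],
           publication_types = ranked$publication_types[[i]],
           rigor_prob = ranked$rigor_prob[i],
           rigor_class = ranked$rigor_class[i],
           context_grade = ranked$context_grade[i],
           pubtype_rank = ranked$pubtype_rank_[i],
           pubtype_grade = ranked$pubtype_grade[i])
    }),
    summaries = lapply(summaries, function(s) {
      list(article_id = s$article_id, study_kind = s$study_kind,
           p_sentences = s$p_sentences, i_sentences = s$i_sentences,
           o_sentences = s$o_sentences, combined = s$combined)
    }),
    evidence_groups = list(article_id = groups$article_id,
                           group = groups$group)
  )
  if (!is.null(output)) {
    writeLines(report_json(report), output, useBytes = TRUE)
    return(invisible(report))
  }
  report
}

#' Serialize a pipeline report to canonical JSON
#'
#' Fixed field order, full numeric precision, no timestamps — two runs with
#' the same inputs, configuration and seed serialize to identical bytes.
#'
#' @param report Report list from [run_pipeline()].
#' @return A JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", pretty = TRUE))
}
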