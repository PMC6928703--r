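# Corpus-level training wrapper: stratified split, vectorization with a
# persisted vocabulary, ensemble fit and held-out evaluation, bundled into a
# single object that classifies new article tibbles.

#' Train the rigor classifier on a labeled corpus
#'
#' Convenience wrapper over [split_corpus()], [vectorize_corpus()],
#' [train_eqrm()] and [evaluate()]: splits the corpus stratified at
#' `spec$split_ratio`, fits the two-level ensemble on the training portion
#' and evaluates on the held-out portion. The fitted vocabulary (with IDF
#' weights) travels with the model so new articles are projected onto the
#' same feature space.
#'
#' @param corpus Labeled article tibble (`label` column, both classes
#'   present).
#' @param spec An [eqrm_spec()].
#' @param scheme Term weighting scheme for [vectorize_corpus()].
#' @return An `eqrm_bundle`: `model`, `vocabulary`, `spec`, `scheme`,
#'   `seed` and the held-out `report`.
#' @export
eqrm_train <- function(corpus, spec = eqrm_spec(), scheme = "tfidf") {
  corpus <- tibble::as_tibble(corpus)
  parts <- split_corpus(corpus, ratio = spec$split_ratio, seed = spec$seed)
  feats <- vectorize_corpus(parts$train, scheme = scheme)
  model <- train_eqrm(feats$matrix, parts$train$label, spec)
  test_feats <- vectorize_corpus(parts$test, scheme = scheme,
                                 vocabulary = feats$vocabulary)
  report <- evaluate(model, test_feats$matrix, parts$test$label)
  structure(list(model = model, vocabulary = feats$vocabulary, spec = spec,
                 scheme = scheme, seed = spec$seed, report = report),
            class = "eqrm_bundle")
}

#' @export
print.eqrm_bundle <- function(x, ...) {
  cat(sprintf("<eqrm_bundle: %s combiner, %d members, |vocab|=%d, seed=%d>\n",
              x$spec$combiner, length(x$model$members),
              nrow(x$vocabulary), x$seed))
  print(x$report)
  invisible(x)
}

#' Score articles with a trained rigor classifier
#'
#' @param bundle An `eqrm_bundle` from [eqrm_train()] or [eqrm_load()].
#' @param records Article tibble.
#' @return The input tibble with `rigor_prob` and `rigor_class` columns
#'   appended.
#' @export
eqrm_classify <- function(bundle, records) {
  stopifnot(inherits(bundle, "eqrm_bundle"))
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    records$rigor_prob <- numeric(0)
    records$rigor_class <- character(0)
    return(records)
  }
  feats <- vectorize_corpus(records, scheme = bundle$scheme,
                            vocabulary = bundle$vocabulary)
  probs <- predict_prob(bundle$model, feats$matrix)
  records$rigor_prob <- probs
  records$rigor_class <- ifelse(probs >= 0.5, "rigor", "nonrigor")
  records
}

#' Persist / restore a trained classifier bundle
#'
#' The bundle (model, vocabulary, spec and seed) is written as a single RDS
#' file.
#'
#' @param bundle An `eqrm_bundle`.
#' @param path File path.
#' @return `path` (save) or the restored bundle (load).
#' @export
eqrm_save <- function(bundle, path) {
  stopifnot(inherits(bundle, "eqrm_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname eqrm_save
#' @export
eqrm_load <- function(path) {
  if (!file.exists(path)) abort(sprintf("model bundle not found: %s", path))
  bundle <- readRDS(path)
  if (!inherits(bundle, "eqrm_bundle")) {
    abort(sprintf("'%s' is not an eqrm bundle", path))
  }
  bundle
}
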