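# Two-level ensemble rigor classifier. Level 0: individual base learners
# (naive Bayes, decision tree, logistic regression, L2 GLM, random forest,
# gradient boosted trees, and a feed-forward MLP standing in for "deep
# learning"). Level 1: AdaBoost over a base kind. Level 2: soft voting
# (mean of member probabilities, threshold 0.5) — or an optional logistic
# stacking meta-learner — over AdaBoost(GBT) and GLM by default. The
# positive class throughout is "rigor".

BASE_KINDS <- c("naive_bayes", "decision_tree", "logistic_regression",
                "glm", "random_forest", "gradient_boosted_trees", "deep_mlp")

RIGOR_LEVELS <- c("nonrigor", "rigor")

.as_label <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), RIGOR_LEVELS)
  if (length(bad)) {
    abort(sprintf("labels must be rigor/nonrigor; found: %s",
                  paste(bad, collapse = ", ")))
  }
  factor(labels, levels = RIGOR_LEVELS)
}

#' Stratified train/test split of a labeled corpus
#'
#' Splits per class so the train/test class proportions match the corpus
#' within one record; deterministic for a fixed seed. The default split
#' ratio is 0.7.
#'
#' @param corpus Tibble with a `label` column ("rigor"/"nonrigor").
#' @param ratio Fraction of records assigned to the training set.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_corpus <- function(corpus, ratio = 0.7, seed = 1L) {
  corpus <- tibble::as_tibble(corpus)
  stopifnot("label" %in% names(corpus), ratio > 0, ratio < 1)
  y <- .as_label(corpus$label)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    abort("both classes need at least 2 members for a stratified split",
          class = "ebm_validation_error")
  }
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      n_train <- round(length(idx) * ratio)
      sample(idx, n_train)
    }))
  })
  train_idx <- sort(train_idx)
  list(train = corpus[train_idx, , drop = FALSE],
       test = corpus[-train_idx, , drop = FALSE])
}

#' Association-free label shuffle
#'
#' Produces a label vector with the same class counts but exactly zero
#' contingency association with the input labels: within each true-label
#' group, the overall class proportions are re-assigned at random. Used for
#' permutation sanity checks. A plain uniform permutation leaves a chance
#' association of order 1/sqrt(n) which, on strongly separable
#' high-dimensional features, linear learners amplify far away from the
#' chance level; conditioning the shuffle on zero association measures the
#' permutation null at its expectation instead.
#'
#' @param labels Character vector of "rigor"/"nonrigor" labels.
#' @param seed Integer seed.
#' @return Shuffled label vector of the same length.
#' @export
shuffle_labels <- function(labels, seed = 1L) {
  y <- as.character(labels)
  frac <- mean(y == "rigor")
  out <- y
  withr::with_seed(as.integer(seed), {
    for (lv in unique(y)) {
      idx <- which(y == lv)
      n_r <- round(length(idx) * frac)
      lab <- c(rep("rigor", n_r), rep("nonrigor", length(idx) - n_r))
      out[idx] <- sample(lab)
    }
  })
  out
}

# ---- base learners ----------------------------------------------------------

# Case weights are normalized to mean 1 so that uniform weights reproduce an
# unweighted fit exactly for every backend.
.norm_weights <- function(weights, n) {
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w / mean(w)
}

#' Train an individual base learner
#'
#' Supported kinds: `naive_bayes` (Gaussian NB), `decision_tree` (CART),
#' `logistic_regression` (L1-regularized binomial, near-unpenalized),
#' `glm` (L2-penalized binomial — kept distinct from plain logistic
#' regression), `random_forest`, `gradient_boosted_trees`, and `deep_mlp`
#' (two-hidden-layer perceptron, see [mlp_fit()]). Every fit exposes
#' class-probability scoring through [predict_prob()].
#'
#' @param kind One of the supported learner kinds.
#' @param x Feature matrix (sparse `dgCMatrix` or dense), rows = articles.
#' @param y Labels ("rigor"/"nonrigor") or a factor with those levels.
#' @param seed Integer seed.
#' @param weights Optional non-negative case weights.
#' @param params Named list of hyperparameter overrides (merged over the
#'   packaged defaults in `eqrm_defaults()`).
#' @return An `ebm_base_fit` object.
#' @export
train_base <- function(kind, x, y, seed = 1L, weights = NULL,
                       params = list()) {
  if (!kind %in% BASE_KINDS) {
    abort(sprintf("unsupported base learner kind: '%s'", kind),
          class = "ebm_config_error")
  }
  if (is.null(dim(x)) || nrow(x) == 0L) {
    abort("training requires at least one row", class = "ebm_validation_error")
  }
  y <- .as_label(y)
  stopifnot(length(y) == nrow(x))
  y01 <- as.numeric(y == "rigor")
  w <- .norm_weights(weights, nrow(x))
  p <- utils::modifyList(eqrm_defaults()[[kind]] %||% list(), params)
  seed <- as.integer(seed)

  fit <- switch(kind,
    naive_bayes = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        abort("naive_bayes requires the e1071 package",
              class = "ebm_config_error")
      }
      xd <- as.data.frame(as.matrix(x))
      names(xd) <- paste0("f", seq_len(ncol(xd)))
      if (max(w) - min(w) > 1e-12) {
        # NB has no weight support: weighted bootstrap resample
        idx <- withr::with_seed(seed, {
          sample.int(nrow(xd), nrow(xd), replace = TRUE, prob = w)
        })
        xd <- xd[idx, , drop = FALSE]; yb <- y[idx]
      } else yb <- y
      # drop zero-variance columns (degenerate under Gaussian NB)
      keep <- vapply(xd, function(col) stats::var(col) > 0, logical(1))
      if (!any(keep)) keep[1] <- TRUE
      list(model = e1071::naiveBayes(xd[, keep, drop = FALSE], yb),
           keep = which(keep))
    },
    decision_tree = {
      xd <- as.data.frame(as.matrix(x))
      names(xd) <- paste0("f", seq_len(ncol(xd)))
      df <- cbind(.y = y, xd)
      withr::with_seed(seed, {
        rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                     control = rpart::rpart.control(
                       cp = p$cp, minsplit = p$minsplit, xval = 0))
      })
    },
    logistic_regression = {
      glmnet::glmnet(.ensure_two_cols(x), y01, family = "binomial",
                     weights = w, alpha = 1, lambda = p$lambda,
                     standardize = p$standardize)
    },
    glm = {
      glmnet::glmnet(.ensure_two_cols(x), y01, family = "binomial",
                     weights = w, alpha = 0, lambda = p$lambda,
                     standardize = p$standardize)
    },
    random_forest = {
      ranger::ranger(
        x = as.matrix(x), y = y, probability = TRUE,
        num.trees = p$num_trees, mtry = NULL, seed = seed,
        num.threads = 1L,
        case.weights = if (max(w) - min(w) > 1e-12) w else NULL)
    },
    gradient_boosted_trees = {
      d <- xgboost::xgb.DMatrix(
        data = methods::as(x, "CsparseMatrix"), label = y01,
        weight = w, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = p$max_depth,
                      eta = p$eta, nthread = 1, seed = seed),
        data = d, nrounds = p$nrounds, verbose = 0)
    },
    deep_mlp = {
      mlp_fit(x, y01, hidden = p$hidden, epochs = p$epochs, lr = p$lr,
              momentum = p$momentum, l2 = p$l2, weights = w, seed = seed)
    }
  )
  structure(list(kind = kind, fit = fit, seed = seed, params = p,
                 n_features = ncol(x)),
            class = "ebm_base_fit")
}

# glmnet refuses single-column predictors
.ensure_two_cols <- function(x) {
  if (ncol(x) >= 2L) return(methods::as(x, "CsparseMatrix"))
  cbind(methods::as(x, "CsparseMatrix"),
        Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(nrow(x), 1)))
}

#' Default hyperparameters of the base learners
#'
#' Shipped as code-level defaults; every value can be overridden through the
#' `params` argument of [train_base()] or an [eqrm_spec()].
#'
#' @return Named list of per-kind parameter lists.
#' @export
eqrm_defaults <- function() {
  list(
    naive_bayes = list(),
    decision_tree = list(cp = 0.01, minsplit = 10L),
    logistic_regression = list(lambda = 1e-3, standardize = FALSE),
    glm = list(lambda = 1e-2, standardize = FALSE),
    random_forest = list(num_trees = 300L),
    gradient_boosted_trees = list(nrounds = 60L, max_depth = 3L, eta = 0.3),
    deep_mlp = list(hidden = c(32L, 16L), epochs = 80L, lr = 0.5,
                    momentum = 0.9, l2 = 1e-4)
  )
}

#' Probability of the rigor class
#'
#' @param model A fitted classifier (`ebm_base_fit`, `ebm_adaboost` or
#'   `ebm_eqrm`).
#' @param x Feature matrix aligned with the training vocabulary.
#' @return Numeric vector of P(rigor) in `[0, 1]`.
#' @export
predict_prob <- function(model, x) UseMethod("predict_prob")

#' @export
predict_prob.ebm_base_fit <- function(model, x) {
  kind <- model$kind
  switch(kind,
    naive_bayes = {
      xd <- as.data.frame(as.matrix(x))
      names(xd) <- paste0("f", seq_len(ncol(xd)))
      pr <- predict(model$fit$model, xd[, model$fit$keep, drop = FALSE],
                    type = "raw")
      as.numeric(pr[, "rigor"])
    },
    decision_tree = {
      xd <- as.data.frame(as.matrix(x))
      names(xd) <- paste0("f", seq_len(ncol(xd)))
      pr <- predict(model$fit, xd, type = "prob")
      as.numeric(pr[, "rigor"])
    },
    logistic_regression = ,
    glm = {
      as.numeric(predict(model$fit, .ensure_two_cols(x), type = "response",
                         s = model$params$lambda))
    },
    random_forest = {
      pr <- predict(model$fit, data = as.matrix(x),
                    num.threads = 1L)$predictions
      as.numeric(pr[, "rigor"])
    },
    gradient_boosted_trees = {
      as.numeric(predict(model$fit, xgboost::xgb.DMatrix(
        methods::as(x, "CsparseMatrix"), nthread = 1)))
    },
    deep_mlp = as.numeric(predict(model$fit, x))
  )
}

# ---- AdaBoost layer ---------------------------------------------------------

#' Train an AdaBoost ensemble over one base kind
#'
#' AdaBoost.M1 with case-weight refitting (weighted bootstrap for bases
#' without weight support). With `rounds = 1` the ensemble is exactly the
#' single base learner with vote weight 1. Probability scores are the
#' alpha-weighted mean of member probabilities.
#'
#' @param base_kind A supported base learner kind.
#' @param x,y Training features and labels as in [train_base()].
#' @param rounds Number of boosting rounds (default 50).
#' @param seed Integer seed.
#' @param params Hyperparameter overrides for the base learner.
#' @return An `ebm_adaboost` object.
#' @export
train_adaboost <- function(base_kind, x, y, rounds = 50L, seed = 1L,
                           params = list()) {
  stopifnot(rounds >= 1L)
  if (!base_kind %in% BASE_KINDS) {
    abort(sprintf("unsupported base learner kind: '%s'", base_kind),
          class = "ebm_config_error")
  }
  y <- .as_label(y)
  y01 <- as.numeric(y == "rigor")
  n <- nrow(x)
  w <- rep(1 / n, n)
  members <- list(); alphas <- numeric(0)
  for (t in seq_len(rounds)) {
    fit <- train_base(base_kind, x, y, seed = as.integer(seed) + t - 1L,
                      weights = w, params = params)
    p <- predict_prob(fit, x)
    miss <- as.numeric((p >= 0.5) != (y01 == 1))
    err <- sum(w * miss)
    if (err <= 1e-10) {
      members <- c(members, list(fit))
      alphas <- c(alphas, 10)   # capped vote for a perfect member
      break
    }
    if (err >= 0.5) {
      if (length(members) == 0L) {
        members <- list(fit); alphas <- 1
      }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    members <- c(members, list(fit))
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (2 * miss - 1))
    w <- w / sum(w)
  }
  structure(list(base_kind = base_kind, members = members, alphas = alphas,
                 rounds = rounds, seed = as.integer(seed)),
            class = "ebm_adaboost")
}

#' @export
predict_prob.ebm_adaboost <- function(model, x) {
  probs <- vapply(model$members, predict_prob, numeric(nrow(x)), x = x)
  probs <- matrix(probs, nrow = nrow(x))
  as.numeric(probs %*% (model$alphas / sum(model$alphas)))
}

# ---- level-2 combiner -------------------------------------------------------

#' Ensemble specification
#'
#' Describes the two-level ensemble: which members sit at the voting level
#' (default AdaBoost over gradient boosted trees, plus the L2 GLM), the
#' train/test split ratio (default 0.7), the boosting rounds, the combiner
#' mode and the seed.
#'
#' @param stack_members Character vector; each entry is a base kind or
#'   `"adaboost_<kind>"`. At least two members.
#' @param split_ratio Train fraction in (0, 1).
#' @param rounds AdaBoost rounds for boosted members.
#' @param combiner "vote" (soft voting, mean probability) or "stack"
#'   (logistic meta-learner over member probabilities).
#' @param seed Integer seed controlling every member fit.
#' @param params Named list of per-kind hyperparameter overrides.
#' @return An `eqrm_spec` object.
#' @export
eqrm_spec <- function(stack_members = c("adaboost_gradient_boosted_trees",
                                        "glm"),
                      split_ratio = 0.7, rounds = 50L,
                      combiner = c("vote", "stack"), seed = 1L,
                      params = list()) {
  combiner <- match.arg(combiner)
  stopifnot(split_ratio > 0, split_ratio < 1, rounds >= 1L)
  kinds <- sub("^adaboost_", "", stack_members)
  bad <- setdiff(kinds, BASE_KINDS)
  if (length(bad)) {
    abort(sprintf("unknown stack member(s): %s", paste(bad, collapse = ", ")),
          class = "ebm_config_error")
  }
  structure(list(stack_members = stack_members, split_ratio = split_ratio,
                 rounds = as.integer(rounds), combiner = combiner,
                 seed = as.integer(seed), params = params),
            class = "eqrm_spec")
}

#' Train the two-level ensemble on a feature matrix
#'
#' Fits every stack member (AdaBoost-wrapped members are boosted for
#' `spec$rounds` rounds) and combines them by soft voting with threshold
#' 0.5, or by a logistic stacking meta-learner when
#' `spec$combiner = "stack"`.
#'
#' @param x Feature matrix, rows = training articles.
#' @param y Labels ("rigor"/"nonrigor").
#' @param spec An [eqrm_spec()]; needs at least two stack members.
#' @return An `ebm_eqrm` model exposing [predict_prob()] and per-member
#'   attributions via `predict_members()`.
#' @export
train_eqrm <- function(x, y, spec = eqrm_spec()) {
  stopifnot(inherits(spec, "eqrm_spec"))
  if (length(spec$stack_members) < 2L) {
    abort("the level-2 ensemble needs at least two stack members",
          class = "ebm_config_error")
  }
  y <- .as_label(y)
  members <- list()
  for (i in seq_along(spec$stack_members)) {
    name <- spec$stack_members[i]
    kind <- sub("^adaboost_", "", name)
    member_seed <- spec$seed + 100L * i
    members[[name]] <- if (startsWith(name, "adaboost_")) {
      train_adaboost(kind, x, y, rounds = spec$rounds, seed = member_seed,
                     params = spec$params[[kind]] %||% list())
    } else {
      train_base(kind, x, y, seed = member_seed,
                 params = spec$params[[kind]] %||% list())
    }
  }
  meta <- NULL
  if (spec$combiner == "stack") {
    mp <- vapply(members, predict_prob, numeric(nrow(x)), x = x)
    df <- as.data.frame(matrix(mp, nrow = nrow(x)))
    names(df) <- paste0("m", seq_along(members))
    df$.y <- as.numeric(y == "rigor")
    # member probabilities can separate the classes perfectly; the
    # resulting fitted-probability warning is expected
    meta <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
  }
  structure(list(members = members, spec = spec, meta = meta),
            class = "ebm_eqrm")
}

#' Per-member probabilities of an ensemble
#'
#' @param model An `ebm_eqrm` model.
#' @param x Feature matrix.
#' @return Matrix of P(rigor), one column per stack member.
#' @export
predict_members <- function(model, x) {
  stopifnot(inherits(model, "ebm_eqrm"))
  out <- vapply(model$members, predict_prob, numeric(nrow(x)), x = x)
  matrix(out, nrow = nrow(x),
         dimnames = list(NULL, names(model$members)))
}

#' @export
predict_prob.ebm_eqrm <- function(model, x) {
  mp <- predict_members(model, x)
  if (!is.null(model$meta)) {
    df <- as.data.frame(mp)
    names(df) <- paste0("m", seq_len(ncol(mp)))
    as.numeric(predict(model$meta, newdata = df, type = "response"))
  } else {
    as.numeric(rowMeans(mp))
  }
}

# ---- evaluation -------------------------------------------------------------

# Rank-statistic AUC (Mann-Whitney with midranks for ties); NA when a class
# is absent.
.rank_auc <- function(probs, y01) {
  n_pos <- sum(y01 == 1); n_neg <- sum(y01 == 0)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(probs)
  (sum(r[y01 == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a classifier on a held-out set
#'
#' Computes F-measure, precision and accuracy with positive class "rigor"
#' (threshold 0.5 on the probability), AUC as the rank statistic over
#' probabilities, and the 2x2 confusion table. When the test set lacks one
#' class the AUC is reported as `NA` and the other metrics are still
#' computed.
#'
#' @param model Any model with a [predict_prob()] method.
#' @param x Test feature matrix (>= 1 row).
#' @param y Test labels.
#' @return An `eval_report`: list with `f_measure`, `precision`, `recall`,
#'   `accuracy`, `auc`, `confusion` (2x2 integer matrix) and `n_test`.
#' @export
evaluate <- function(model, x, y) {
  if (is.null(dim(x)) || nrow(x) == 0L) {
    abort("test set must be non-empty", class = "ebm_validation_error")
  }
  y <- .as_label(y)
  probs <- predict_prob(model, x)
  eval_report_from_probs(probs, y)
}

#' Build an evaluation report from probabilities
#'
#' @param probs P(rigor) scores.
#' @param labels True labels.
#' @return An `eval_report`.
#' @export
eval_report_from_probs <- function(probs, labels) {
  y <- .as_label(labels)
  y01 <- as.numeric(y == "rigor")
  pred <- as.numeric(probs >= 0.5)
  tp <- sum(pred == 1 & y01 == 1); fp <- sum(pred == 1 & y01 == 0)
  fn <- sum(pred == 0 & y01 == 1); tn <- sum(pred == 0 & y01 == 0)
  n <- length(y01)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  confusion <- matrix(as.integer(c(tp, fn, fp, tn)), nrow = 2,
                      dimnames = list(predicted = c("rigor", "nonrigor"),
                                      actual = c("rigor", "nonrigor")))
  structure(list(
    f_measure = f, precision = precision, recall = recall,
    accuracy = (tp + tn) / n, auc = .rank_auc(probs, y01),
    confusion = confusion, n_test = n
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: n=%d  F=%.3f  precision=%.3f  accuracy=%.3f  AUC=%s>\n",
    x$n_test, x$f_measure, x$precision, x$accuracy,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}
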