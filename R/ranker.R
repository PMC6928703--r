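# Evidence grading and contextual ranking. Grades form the total order
# H > M > L > U (U is the bottom element). Publication types carry a rank
# 1-11 and a grade band (H for ranks 1-3, M for 4-7, L for 8-11); user and
# evidence contexts meet in a grade matrix whose columns are aggregated by
# majority vote (ties toward the higher grade) and whose best aggregate is
# the article's cross-context grade.

#' The ordered evidence grade scale
#'
#' @return Character vector `c("U","L","M","H")`, worst to best.
#' @export
grade_levels <- function() GRADE_LEVELS

.grade_value <- function(g) {
  v <- match(g, GRADE_LEVELS)
  if (anyNA(v)) {
    abort(sprintf("invalid grade(s): %s",
                  paste(unique(g[is.na(v)]), collapse = ", ")))
  }
  v
}

#' Majority-vote aggregate of a grade column
#'
#' Returns the most frequent grade in the column; ties are broken toward
#' the higher grade in the H > M > L > U order. Invariant to cell order.
#'
#' @param cells Character vector of grades (>= 1 cell).
#' @return A single grade.
#' @export
aggregate_column <- function(cells) {
  stopifnot(length(cells) >= 1L)
  vals <- .grade_value(cells)
  counts <- tabulate(vals, nbins = length(GRADE_LEVELS))
  top <- which(counts == max(counts))
  GRADE_LEVELS[max(top)]
}

#' Cross-context grade of a context matrix
#'
#' Aggregates every column of the user-by-evidence grade matrix with
#' [aggregate_column()] (the vertical step), then returns the highest
#' aggregate (the horizontal step).
#'
#' @param matrix A character matrix or data frame of grades; rows are user
#'   context parameters, columns are evidence properties.
#' @return A single grade.
#' @export
cross_context_grade <- function(matrix) {
  m <- as.matrix(matrix)
  stopifnot(nrow(m) >= 1L, ncol(m) >= 1L)
  aggs <- apply(m, 2L, aggregate_column)
  GRADE_LEVELS[max(.grade_value(aggs))]
}

#' Shipped publication-type ranking table
#'
#' Eleven rows mapping publication types to an evidence rank (1 = best) and
#' grade band; editable JSON under `extdata/config/pubtype_ranks.json`.
#' Each row lists normalized aliases used to match MEDLINE publication-type
#' strings.
#'
#' @param path Optional alternative JSON table.
#' @return Tibble with columns `name`, `rank`, `grade`, `aliases` (list).
#' @export
pubtype_rank_table <- function(path = NULL) {
  path <- path %||% ebm_extdata("config", "pubtype_ranks.json")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dplyr::bind_rows(lapply(raw, function(r) {
    tibble::tibble(name = r$name, rank = as.integer(r$rank),
                   grade = r$grade,
                   aliases = list(as.character(unlist(r$aliases))))
  }))
}

#' Rank and grade an article by its publication types
#'
#' The best (minimum) rank over the article's listed types wins; a type not
#' covered by the table, or an empty type list, falls to the
#' "any other publication type" row (rank 11, grade L).
#'
#' @param pub_types Character vector of publication-type strings.
#' @param table Table from [pubtype_rank_table()].
#' @return List with `rank` (integer) and `grade`.
#' @export
pubtype_rank <- function(pub_types, table = pubtype_rank_table()) {
  fallback <- table[table$rank == max(table$rank), ][1L, ]
  if (length(pub_types) == 0L) {
    return(list(rank = fallback$rank, grade = fallback$grade))
  }
  norm <- normalize_term(pub_types)
  best <- fallback
  for (i in seq_len(nrow(table))) {
    keys <- normalize_term(c(table$name[i], table$aliases[[i]]))
    if (any(norm %in% keys) && table$rank[i] < best$rank) {
      best <- table[i, ]
    }
  }
  list(rank = best$rank, grade = best$grade)
}

# year -> recency grade, relative to a reference year
.recency_grade <- function(year, ref_year) {
  if (is.na(year)) return("U")
  age <- ref_year - year
  if (age <= 5) "H" else if (age <= 10) "M" else "L"
}

#' Rank classified articles under a user context
#'
#' For each article, the evidence properties are graded (P1 = publication
#' type via [pubtype_rank()]; P2 = recency: H within 5 years of the newest
#' article in the set, M within 10, L older, U unknown). Each cell of the
#' context matrix is the grade-scale minimum of the user context element
#' and the evidence property, the matrix is collapsed with
#' [cross_context_grade()], and articles are sorted by (cross-context grade
#' desc, publication-type rank asc, rigor probability desc, year desc),
#' stably.
#'
#' @param articles Tibble with `article_id`, `publication_types`, `year`
#'   and `rigor_prob` columns (e.g., from [eqrm_classify()]).
#' @param user_context Named character vector or tibble column of grades,
#'   one per user context element (education, background, goal, interest,
#'   learning style, ...), each in H/M/L/U. Default: a single neutral "H"
#'   element, which reduces ranking to the evidence side.
#' @param table Publication-type table.
#' @param ref_year Reference year for recency; default the newest year in
#'   `articles`.
#' @return The input tibble, ranked, with `context_grade`, `pubtype_rank_`
#'   and `pubtype_grade` columns appended.
#' @export
rank_articles <- function(articles, user_context = c(context = "H"),
                          table = pubtype_rank_table(), ref_year = NULL) {
  articles <- tibble::as_tibble(articles)
  if (nrow(articles) == 0L) {
    articles$context_grade <- character(0)
    articles$pubtype_rank_ <- integer(0)
    articles$pubtype_grade <- character(0)
    return(articles)
  }
  stopifnot(all(c("article_id", "publication_types", "year") %in%
                  names(articles)))
  if (!"rigor_prob" %in% names(articles)) articles$rigor_prob <- NA_real_
  uc <- as.character(user_context)
  .grade_value(uc)   # validate
  ref_year <- ref_year %||% suppressWarnings(max(articles$year, na.rm = TRUE))

  pr <- lapply(articles$publication_types, pubtype_rank, table = table)
  articles$pubtype_rank_ <- vapply(pr, `[[`, integer(1), "rank")
  articles$pubtype_grade <- vapply(pr, `[[`, character(1), "grade")

  articles$context_grade <- vapply(seq_len(nrow(articles)), function(i) {
    evidence <- c(articles$pubtype_grade[i],
                  .recency_grade(articles$year[i], ref_year))
    cells <- outer(.grade_value(uc), .grade_value(evidence), pmin)
    m <- matrix(GRADE_LEVELS[cells], nrow = length(uc))
    cross_context_grade(m)
  }, character(1))

  prob_key <- ifelse(is.na(articles$rigor_prob), -1, articles$rigor_prob)
  year_key <- ifelse(is.na(articles$year), 0L, articles$year)
  ord <- order(-.grade_value(articles$context_grade),
               articles$pubtype_rank_,
               -prob_key,
               -year_key)
  articles[ord, , drop = FALSE]
}
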