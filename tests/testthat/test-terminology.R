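# Terminology store and the weighted STI matcher.

single_store <- function() {
  terminology_store(tibble::tibble(
    concept_id = "X1", preferred_name = "female",
    synonyms = list(character(0)), semantic_types = list("population group"),
    entity_type = "population group", parent_ids = list(character(0))
  ))
}

test_that("a single-record fixture loads and resolves", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"id":"X1","name":"female","synonyms":[],
    "semantic_types":["population group"],"entity_type":"population group",
    "parents":[]}]', path)
  store <- load_terminology(path)
  expect_equal(length(store), 1L)
  m <- sti_match("female", store)
  expect_equal(m$concept_id, "X1")
  expect_equal(m$weight, 1.0)
})

test_that("duplicate ids and dangling parents are integrity errors", {
  dup <- tibble::tibble(
    concept_id = c("A", "A"), preferred_name = c("one", "two"),
    synonyms = list(character(0), character(0)),
    semantic_types = list("finding", "finding"),
    entity_type = "finding", parent_ids = list(character(0), character(0))
  )
  expect_error(terminology_store(dup), class = "ebm_integrity_error")

  dangling <- tibble::tibble(
    concept_id = "A", preferred_name = "one",
    synonyms = list(character(0)), semantic_types = list("finding"),
    entity_type = "finding", parent_ids = list("MISSING")
  )
  expect_error(terminology_store(dangling), class = "ebm_integrity_error")

  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", path)
  expect_error(load_terminology(path), class = "ebm_parse_error")
})

test_that("match levels carry the STI weights 1.0 / 0.5 / 0", {
  store <- demo_store()
  exact <- sti_match("female", store)
  expect_equal(exact$match_level, "exact")
  expect_equal(exact$weight, 1.0)

  syn <- sti_match("ACE inhibitor", store)
  expect_equal(syn$match_level, "synonym")
  expect_equal(syn$weight, 0.5)
  expect_equal(syn$concept_id, "C004")

  part <- sti_match("raised blood pressure", store)
  expect_equal(part$match_level, "partial")
  expect_equal(part$weight, 0.5)
  expect_equal(part$concept_id, "C002")

  none <- sti_match("zzqx", store)
  expect_equal(none$match_level, "none")
  expect_equal(none$weight, 0)
  expect_true(is.na(none$concept_id))

  expect_error(sti_match("", store))
})

test_that("exact beats synonym beats partial when several levels apply", {
  store <- terminology_store(tibble::tibble(
    concept_id = c("A1", "A2", "A3"),
    preferred_name = c("heart failure", "cardiac decompensation",
                       "heart failure therapy"),
    synonyms = list(character(0), "heart failure", character(0)),
    semantic_types = list("disease or syndrome", "disease or syndrome",
                          "therapeutic or preventive procedure"),
    entity_type = "disorder",
    parent_ids = list(character(0), character(0), character(0))
  ))
  # "heart failure" is A1's preferred name, A2's synonym, and a token
  # subset of A3's name: exact must win
  m <- sti_match("heart failure", store)
  expect_equal(m$concept_id, "A1")
  expect_equal(m$match_level, "exact")
})

test_that("same-level ties go to the longest name, then the smallest id", {
  store <- terminology_store(tibble::tibble(
    concept_id = c("B2", "B1"),
    preferred_name = c("hypertension", "hypertension"),
    synonyms = list(character(0), character(0)),
    semantic_types = list("disease or syndrome", "disease or syndrome"),
    entity_type = "disorder",
    parent_ids = list(character(0), character(0))
  ))
  expect_equal(sti_match("hypertension", store)$concept_id, "B1")

  store2 <- terminology_store(tibble::tibble(
    concept_id = c("P1", "P2"),
    preferred_name = c("blood pressure measurement",
                       "blood pressure measurement protocol"),
    synonyms = list(character(0), character(0)),
    semantic_types = list("finding", "finding"),
    entity_type = "finding",
    parent_ids = list(character(0), character(0))
  ))
  # both partial-match "blood pressure"; the longer matched name wins
  expect_equal(sti_match("blood pressure", store2)$concept_id, "P2")
})

test_that("parent lookups are one level deep and fixture-ordered", {
  store <- demo_store()
  expect_equal(nrow(parent_concepts("C001", store)), 0L)
  p <- parent_concepts("C003", store)
  expect_equal(p$preferred_name, "antihypertensive agent")
  expect_error(parent_concepts("NOPE", store), class = "ebm_lookup_error")

  chain <- terminology_store(tibble::tibble(
    concept_id = c("C", "B", "A"),
    preferred_name = c("c", "b", "a"),
    synonyms = list(character(0), character(0), character(0)),
    semantic_types = list("finding", "finding", "finding"),
    entity_type = "finding",
    parent_ids = list(character(0), list("C")[[1]], list("B")[[1]])
  ))
  expect_equal(parent_concepts("A", chain)$concept_id, "B")
})

test_that("sti_match agrees with a brute-force scan and is idempotent", {
  store <- demo_store()
  probes <- c(
    store$concepts$preferred_name,
    unlist(store$concepts$synonyms),
    "raised blood pressure", "blood", "inhibitor drug", "pressure",
    "beta", "diabetes", "chronic pulmonary", "zzqx", "the"
  )
  for (term in probes) {
    got <- sti_match(term, store)
    want <- sti_bruteforce(term, store)
    expect_equal(got$match_level, want$level, info = term)
    expect_equal(got$weight, want$weight, info = term)
    if (want$level != "none") {
      expect_equal(got$concept_id, want$id, info = term)
    }
    expect_identical(got, sti_match(term, store))
    expect_true(got$weight %in% c(1, 0.5, 0))
  }
})
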