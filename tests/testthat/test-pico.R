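# PICO question construction from text, rules and structured records.

test_that("the worked hypertension scenario maps to the expected slots", {
  store <- demo_store()
  q <- pico_from_text(demo_scenario_text(), store)
  p <- pico_slot(q, "P")
  expect_true(all(c("C001", "C002") %in% p$concept_id))  # female, blood pressure
  expect_equal(pico_slot(q, "I")$concept_id, "C003")     # beta-blocker first
  expect_equal(pico_slot(q, "C")$concept_id, "C004")     # ACE inhibitor second
  expect_equal(q$query_type, "treatment")
  expect_true(is_searchable(q))
})

test_that("stopword-only text yields an empty, unsearchable question", {
  q <- pico_from_text("the of and", demo_store())
  expect_equal(nrow(q$terms), 0L)
  expect_false(is_searchable(q))
  expect_error(pico_from_text("", demo_store()))
})

test_that("a single population term fills only the P slot", {
  q <- pico_from_text("female", demo_store())
  expect_equal(pico_slot(q, "P")$surface, "female")
  expect_equal(nrow(pico_slot(q, "I")), 0L)
  expect_equal(nrow(pico_slot(q, "C")), 0L)
  expect_equal(nrow(pico_slot(q, "O")), 0L)
})

test_that("slot assignment follows semantic/entity types with I-then-C", {
  store <- demo_store()
  female <- store$concepts[store$concepts$concept_id == "C001", ]
  expect_equal(assign_slot(female), "P")
  drug <- store$concepts[store$concepts$concept_id == "C003", ]
  expect_equal(assign_slot(drug, have_intervention = FALSE), "I")
  expect_equal(assign_slot(drug, have_intervention = TRUE), "C")

  unknown <- tibble::tibble(
    concept_id = "U1", preferred_name = "mystery",
    synonyms = list(character(0)), semantic_types = list("weird type"),
    entity_type = "weird type", parent_ids = list(character(0)))
  expect_warning(slot <- assign_slot(unknown), "defaulting to P")
  expect_equal(slot, "P")
})

test_that("rule elements map D -> P, A -> I/C, purpose -> O", {
  rule <- knowledge_rule(
    data_elements = "hypertension",
    action_elements = c("beta-blocker", "ACE inhibitor"),
    purpose = "lower blood pressure")
  q <- pico_from_rule(rule, store = demo_store())
  expect_equal(pico_slot(q, "P")$surface, "hypertension")
  expect_equal(pico_slot(q, "I")$surface, "beta-blocker")
  expect_equal(pico_slot(q, "C")$surface, "ACE inhibitor")
  expect_equal(pico_slot(q, "O")$surface, "lower blood pressure")
  expect_equal(q$query_type, "treatment")

  no_purpose <- knowledge_rule("hypertension", "beta-blocker")
  q2 <- pico_from_rule(no_purpose, store = demo_store())
  expect_equal(nrow(pico_slot(q2, "O")), 0L)

  expect_error(knowledge_rule(character(0), "x"),
               class = "ebm_validation_error")
})

test_that("rule mapping is invariant to data-element order", {
  a <- pico_from_rule(knowledge_rule(c("hypertension", "diabetes mellitus"),
                                     "beta-blocker"), store = demo_store())
  b <- pico_from_rule(knowledge_rule(c("diabetes mellitus", "hypertension"),
                                     "beta-blocker"), store = demo_store())
  expect_identical(a$terms, b$terms)
})

test_that("structured records pass through STI for standardization only", {
  q <- pico_from_record(
    list(problem = "hypertension", intervention = "beta-blocker",
         comparison = "ACE inhibitor"),
    store = demo_store())
  expect_equal(pico_slot(q, "P")$concept_id, "C006")
  expect_equal(pico_slot(q, "I")$weight, 1.0)
  expect_equal(pico_slot(q, "C")$weight, 0.5)   # synonym-standardized
  expect_equal(q$query_type, "treatment")
})

test_that("query type is the majority vote over I/C parent translations", {
  store <- demo_store()
  # both drugs share the antihypertensive-agent parent -> treatment
  q <- pico_from_text("beta-blocker or ACE inhibitor therapy", store)
  expect_equal(identify_query_type(q, store), "treatment")

  # no I/C concepts -> unknown
  q_empty <- pico_from_text("female", store)
  expect_equal(identify_query_type(q_empty, store), "unknown")

  # 2 treatment votes vs 1 diagnosis vote -> treatment
  votes_store <- terminology_store(tibble::tibble(
    concept_id = c("T", "D", "d1", "d2", "d3"),
    preferred_name = c("therapeutic agent", "diagnostic procedure",
                       "drug one", "drug two", "assay three"),
    synonyms = list(character(0), character(0), character(0), character(0),
                    character(0)),
    semantic_types = list("pharmacologic substance", "diagnostic procedure",
                          "pharmacologic substance", "pharmacologic substance",
                          "pharmacologic substance"),
    entity_type = "chemical and drugs",
    parent_ids = list(character(0), character(0), "T", "T", "D")
  ))
  q3 <- pico_question(tibble::tibble(
    surface = c("drug one", "drug two", "assay three"),
    concept_id = c("d1", "d2", "d3"), weight = 1,
    slot = c("I", "C", "C")))
  expect_equal(identify_query_type(q3, votes_store), "treatment")

  # 1-1 tie resolves by the fixed priority (treatment first)
  q4 <- pico_question(tibble::tibble(
    surface = c("drug one", "assay three"),
    concept_id = c("d1", "d3"), weight = 1, slot = c("I", "C")))
  expect_equal(identify_query_type(q4, votes_store), "treatment")
})

test_that("adding a majority-confirming concept never changes the vote", {
  store <- demo_store()
  base <- pico_question(tibble::tibble(
    surface = "beta blocker x", concept_id = "C003", weight = 1, slot = "I"))
  before <- identify_query_type(base, store)
  grown <- pico_question(tibble::tibble(
    surface = c("beta blocker x", "ace inhibitor y"),
    concept_id = c("C003", "C004"), weight = 1, slot = c("I", "C")))
  expect_equal(identify_query_type(grown, store), before)
})

test_that("slot partition holds: no surface term in two slots", {
  q <- pico_from_text(demo_scenario_text(), demo_store())
  expect_false(anyDuplicated(q$terms$surface) > 0)
  expect_error(pico_question(tibble::tibble(
    surface = c("x", "x"), concept_id = NA_character_, weight = 0,
    slot = c("P", "I"))))
})
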