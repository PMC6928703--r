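# Deterministic generators for everything the test suite and the demos
# need: a demo terminology covering the worked hypertension scenario, a
# small MEDLINE-style article set, and a seeded synthetic labeled corpus
# with controllable class separation. The synthetic corpus stands in for a
# licensed manually-annotated gold standard: the rigor signal it encodes —
# distributional differences in abstract wording plus trial-like metadata
# (randomized-trial publication types, random-allocation indexing terms) —
# mirrors what methodological-rigor criteria look like in MEDLINE records.

.demo_concepts <- function() {
  con <- function(id, name, syn = character(0), stype, etype = stype,
                  parents = character(0)) {
    tibble::tibble(concept_id = id, preferred_name = name,
                   synonyms = list(syn), semantic_types = list(stype),
                   entity_type = etype[1], parent_ids = list(parents))
  }
  drugs <- c(insulin = "insulin", metformin = "metformin",
             albuterol = "albuterol", aspirin = "aspirin",
             simvastatin = "simvastatin", warfarin = "warfarin",
             amoxicillin = "amoxicillin", fluoxetine = "fluoxetine",
             sumatriptan = "sumatriptan", alendronate = "alendronate")
  diseases <- c(diabetes = "diabetes mellitus", asthma = "asthma",
                mi = "myocardial infarction", stroke = "stroke",
                afib = "atrial fibrillation", pneumonia = "pneumonia",
                depression = "depression", osteoporosis = "osteoporosis",
                migraine = "migraine", anemia = "anemia",
                copd = "chronic obstructive pulmonary disease")
  dplyr::bind_rows(
    con("C001", "female", stype = "population group"),
    con("C002", "blood pressure", stype = "finding"),
    con("C003", "beta-blocker", syn = c("beta blocking agent"),
        stype = "pharmacologic substance", etype = "chemical and drugs",
        parents = "C005"),
    con("C004", "angiotensin-converting-enzyme inhibitor",
        syn = c("ACE inhibitor"),
        stype = "pharmacologic substance", etype = "chemical and drugs",
        parents = "C005"),
    con("C005", "antihypertensive agent",
        stype = "pharmacologic substance", etype = "chemical and drugs"),
    con("C006", "hypertension", stype = "disease or syndrome",
        etype = "disorder"),
    con("C007", "therapeutic agent", stype = "pharmacologic substance",
        etype = "chemical and drugs"),
    dplyr::bind_rows(purrr::imap(drugs, function(name, key) {
      con(paste0("D", sprintf("%03d", match(key, names(drugs)))), name,
          stype = "pharmacologic substance", etype = "chemical and drugs",
          parents = "C007")
    })),
    dplyr::bind_rows(purrr::imap(diseases, function(name, key) {
      con(paste0("S", sprintf("%03d", match(key, names(diseases)))), name,
          stype = "disease or syndrome", etype = "disorder")
    }))
  )
}

#' Generate the demo terminology fixture
#'
#' A deterministic vocabulary covering the worked hypertension scenario —
#' female (population group), blood pressure (finding), beta-blocker and
#' ACE inhibitor (chemical and drugs, sharing the parent "antihypertensive
#' agent", which translates to the treatment query type) — plus 20+
#' distractor concepts that never match the scenario terms. Repeated
#' generation is byte-identical.
#'
#' @param path Optional path; when given, the fixture is also written there
#'   as terminology JSON readable by [load_terminology()].
#' @return A [terminology_store()].
#' @export
make_terminology_fixture <- function(path = NULL) {
  concepts <- .demo_concepts()
  if (!is.null(path)) {
    recs <- lapply(seq_len(nrow(concepts)), function(i) {
      list(id = concepts$concept_id[i], name = concepts$preferred_name[i],
           synonyms = concepts$synonyms[[i]],
           semantic_types = concepts$semantic_types[[i]],
           entity_type = concepts$entity_type[i],
           parents = concepts$parent_ids[[i]])
    })
    writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE),
               path, useBytes = TRUE)
  }
  terminology_store(concepts)
}

#' The demo clinical scenario
#'
#' Free-text scenario used in examples and tests: an elderly female patient
#' with raised blood pressure on a beta-blocker, where an ACE inhibitor is
#' the candidate alternative.
#'
#' @return A single string.
#' @export
demo_scenario_text <- function() {
  paste(
    "A 65 year old female patient presents with raised blood pressure",
    "despite treatment with a beta-blocker.",
    "The physician asks whether switching to an ACE inhibitor would",
    "achieve better control of the blood pressure."
  )
}

#' Deterministic demo article set
#'
#' Twelve hand-written MEDLINE-style records about antihypertensive
#' treatment and unrelated topics, spanning publication types from
#' systematic review to opinion piece; several match the demo scenario
#' query. Used by examples and the offline pipeline.
#'
#' @return Article tibble in the [parse_medline_xml()] layout.
#' @export
make_demo_articles <- function() {
  rec <- function(id, title, abstract, mesh, ptypes, journal, year) {
    tibble::tibble(article_id = id, title = title, abstract = abstract,
                   mesh_terms = list(mesh), publication_types = list(ptypes),
                   journal = journal, year = as.integer(year))
  }
  dplyr::bind_rows(
    rec("900001",
        "Beta-blocker versus ACE inhibitor therapy in female patients with elevated blood pressure",
        paste("Elevated blood pressure in female patients often requires a",
              "change of therapy. We randomized participants to a",
              "beta-blocker or an ACE inhibitor arm.",
              "Blood pressure control was the primary outcome.",
              "The ACE inhibitor group achieved lower blood pressure."),
        c("Hypertension", "Adrenergic beta-Antagonists",
          "Angiotensin-Converting Enzyme Inhibitors", "Female"),
        c("Randomized Controlled Trial", "Journal Article"),
        "Journal of Hypertension", 2019),
    rec("900002",
        "Systematic review of antihypertensive drug classes in women",
        paste("We reviewed trials comparing antihypertensive drug classes.",
              "Beta-blocker and ACE inhibitor regimens were compared for",
              "blood pressure reduction in female participants."),
        c("Hypertension", "Female", "Antihypertensive Agents"),
        c("Systematic Review"),
        "Cochrane Database", 2021),
    rec("900003",
        "ACE inhibitor adherence and blood pressure outcomes in a female cohort",
        paste("A cohort of female patients using an ACE inhibitor was",
              "followed for two years. Blood pressure outcomes improved",
              "with adherence."),
        c("Medication Adherence", "Female", "Blood Pressure"),
        c("Cohort Study", "Journal Article"),
        "BMJ Open", 2020),
    rec("900004",
        "Meta-analysis of randomized trials of beta-blockers after myocardial infarction",
        paste("We pooled randomized trials of beta-blocker therapy after",
              "myocardial infarction and estimated mortality effects."),
        c("Myocardial Infarction", "Adrenergic beta-Antagonists"),
        c("Meta-Analysis", "Journal Article"),
        "The Lancet", 2018),
    rec("900005",
        "Expert opinion: first-line drugs for raised blood pressure",
        paste("An opinion on choosing first-line therapy for raised blood",
              "pressure, including beta-blocker and ACE inhibitor options",
              "in female patients."),
        c("Hypertension", "Drug Therapy"),
        c("Editorial"),
        "Family Practice News", 2022),
    rec("900006",
        "Blood pressure measurement technique in clinical practice",
        paste("Accurate blood pressure measurement underpins hypertension",
              "care. We describe cuff placement and timing."),
        c("Blood Pressure Determination"),
        c("Journal Article"),
        "Clinical Methods", 2015),
    rec("900007",
        "Metformin versus insulin for glycemic control in type 2 diabetes",
        paste("A randomized trial comparing metformin with insulin for",
              "glycemic control in adults with type 2 diabetes."),
        c("Diabetes Mellitus, Type 2", "Metformin", "Insulin"),
        c("Randomized Controlled Trial"),
        "Diabetes Care", 2017),
    rec("900008",
        "Asthma exacerbations and inhaled therapy: an observational study",
        paste("We observed exacerbation rates under inhaled therapy in an",
              "asthma registry."),
        c("Asthma"),
        c("Observational Study"),
        "Respiratory Medicine", 2016),
    rec("900009",
        "Guideline: management of newly diagnosed hypertension",
        paste("Consensus guideline on the management of newly diagnosed",
              "hypertension, covering lifestyle and drug therapy including",
              "ACE inhibitor use."),
        c("Hypertension", "Practice Guidelines as Topic"),
        c("Practice Guideline"),
        "National Guideline Clearinghouse", 2020),
    rec("900010",
        "Warfarin dosing in atrial fibrillation: a controlled trial",
        paste("A controlled trial of warfarin dosing strategies in atrial",
              "fibrillation."),
        c("Atrial Fibrillation", "Warfarin"),
        c("Controlled Clinical Trial"),
        "Circulation", 2014),
    rec("900011",
        "Blood pressure variability in elderly female patients: case report",
        paste("We report a case of marked blood pressure variability in an",
              "elderly female patient on a beta-blocker."),
        c("Blood Pressure", "Female", "Aged"),
        c("Case Reports"),
        "Case Reports in Medicine", 2023),
    rec("900012",
        "Depression screening in primary care",
        "",
        c("Depression", "Mass Screening"),
        c("Journal Article"),
        "Primary Care", 2021)
  )
}

# ---- synthetic labeled corpus ----------------------------------------------

#' Specification of a synthetic labeled corpus
#'
#' @param n_articles Number of articles (>= 20).
#' @param rigor_fraction Fraction of rigor articles, in (0, 1). The default
#'   0.5 keeps the benchmark corpus balanced so the no-information rate is
#'   0.5; real indexed literature is rigor-minority, which can be emulated
#'   by setting the fraction explicitly.
#' @param separation Class separation: "high", "medium" or "low".
#' @param vocab_size Size of the synthetic vocabulary (default 400).
#' @param seed Integer seed; the corpus is fully determined by it.
#' @return A `corpus_spec` object.
#' @export
corpus_spec <- function(n_articles = 2000L, rigor_fraction = 0.5,
                        separation = c("high", "medium", "low"),
                        vocab_size = 400L, seed = 1L) {
  separation <- match.arg(separation)
  n_articles <- as.integer(n_articles)
  if (is.na(n_articles) || n_articles < 20L) {
    abort("n_articles must be at least 20", class = "ebm_validation_error")
  }
  if (!(rigor_fraction > 0 && rigor_fraction < 1)) {
    abort("rigor_fraction must lie in (0, 1)", class = "ebm_validation_error")
  }
  if (vocab_size < 60L) {
    abort("vocab_size must be at least 60", class = "ebm_validation_error")
  }
  structure(list(n_articles = n_articles, rigor_fraction = rigor_fraction,
                 separation = separation, vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# pseudo-words built from syllables; no common English suffixes, all longer
# than 3 characters, so they pass the stopword and length filters and are
# left essentially intact by the stemmer
.synthetic_vocab <- function(size) {
  syl <- c("ba", "de", "fi", "go", "hu", "ka", "lo", "mi", "nu", "pa",
           "re", "so", "tu", "va", "wo", "za", "ce", "di", "fo", "gu")
  words <- character(size)
  for (k in seq_len(size)) {
    i1 <- ((k - 1L) %% 20L) + 1L
    i2 <- ((k - 1L) %/% 20L) %% 20L + 1L
    i3 <- ((k - 1L) %/% 400L) %% 20L + 1L
    words[k] <- paste0(syl[i1], syl[i2], syl[i3], "x")
  }
  words
}

# class-separation settings: token tilt factor and the probability that a
# rigor article carries trial-like metadata
.separation_params <- function(separation) {
  switch(separation,
    high = list(tilt = 6, meta_p = 0.9),
    medium = list(tilt = 2.2, meta_p = 0.72),
    low = list(tilt = 1.05, meta_p = 0.52)
  )
}

#' Generate a synthetic rigor/nonrigor corpus
#'
#' Generative model: per class, abstract and title tokens are drawn from a
#' multinomial over a shared Zipf-shaped pseudo-word vocabulary; a block of
#' signal tokens is up-weighted by a tilt factor in the rigor class and a
#' disjoint block in the nonrigor class, so the divergence between the two
#' distributions is set by `separation`. Rigor articles additionally
#' receive trial-like metadata (a "Randomized Controlled Trial" publication
#' type and a "Random Allocation" indexing term) with a
#' separation-dependent probability, so the signal lives in both the data
#' features and the metadata features. Class balance matches
#' `rigor_fraction` within one article, and the corpus is fully determined
#' by the seed.
#'
#' @param spec A [corpus_spec()].
#' @return Labeled article tibble (with `label` column).
#' @export
make_synthetic_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  pars <- .separation_params(spec$separation)
  vocab <- .synthetic_vocab(spec$vocab_size)
  base <- 1 / (seq_len(spec$vocab_size) + 10)
  n_sig <- 20L
  sig_rigor <- seq_len(n_sig)
  sig_nonrigor <- n_sig + seq_len(n_sig)
  p_rigor <- base; p_rigor[sig_rigor] <- p_rigor[sig_rigor] * pars$tilt
  p_non <- base; p_non[sig_nonrigor] <- p_non[sig_nonrigor] * pars$tilt
  p_rigor <- p_rigor / sum(p_rigor); p_non <- p_non / sum(p_non)

  n_rigor <- round(spec$n_articles * spec$rigor_fraction)
  labels <- c(rep("rigor", n_rigor),
              rep("nonrigor", spec$n_articles - n_rigor))
  journals <- c("Synthetic Journal of Trials", "Annals of Synthetic Medicine",
                "Synthetic Clinical Review")
  neutral_mesh <- c("Humans", "Adult", "Treatment Outcome", "Follow-Up Studies",
                    "Prospective Studies")

  withr::with_seed(spec$seed, {
    labels <- sample(labels)
    rows <- lapply(seq_len(spec$n_articles), function(i) {
      p <- if (labels[i] == "rigor") p_rigor else p_non
      abstract_toks <- sample(vocab, 90L, replace = TRUE, prob = p)
      title_toks <- sample(vocab, 8L, replace = TRUE, prob = p)
      sent <- split(abstract_toks,
                    ceiling(seq_along(abstract_toks) / 12L))
      abstract <- paste(vapply(sent, function(s) {
        s1 <- paste(s, collapse = " ")
        paste0(toupper(substr(s1, 1, 1)), substr(s1, 2, nchar(s1)), ".")
      }, character(1)), collapse = " ")
      trial_meta <- stats::rbinom(1, 1,
        if (labels[i] == "rigor") pars$meta_p else 1 - pars$meta_p) == 1
      ptypes <- if (trial_meta) {
        c("Randomized Controlled Trial", "Journal Article")
      } else "Journal Article"
      mesh <- c(sample(neutral_mesh, 2L),
                if (trial_meta) "Random Allocation")
      tibble::tibble(
        article_id = sprintf("SYN%06d", i),
        title = paste(title_toks, collapse = " "),
        abstract = abstract,
        mesh_terms = list(mesh),
        publication_types = list(ptypes),
        journal = sample(journals, 1L),
        year = sample(2000:2023, 1L),
        label = labels[i]
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Offline search backend over article records
#'
#' Thin alias of [fixture_backend()]: builds the deterministic in-memory
#' backend the tests and the offline pipeline run against.
#'
#' @param records Article tibble.
#' @return A `fixture_backend`.
#' @export
make_fixture_backend <- function(records) fixture_backend(records)
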