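# MEDLINE parsing, feature maps and corpus vectorization.

test_that("the packaged 3-record fixture parses with known titles", {
  recs <- parse_medline_xml(ebm_extdata("medline_sample.xml"))
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$article_id, c("900001", "900002", "900003"))
  expect_match(recs$title[1], "Beta-blocker versus ACE inhibitor")
  expect_true("Systematic Review" %in% recs$publication_types[[2]])
  expect_true("Hypertension" %in% recs$mesh_terms[[1]])
})

test_that("missing abstracts, empty sets and bad records are handled", {
  xml <- '<PubmedArticleSet><PubmedArticle><MedlineCitation>
    <PMID>42</PMID><Article><ArticleTitle>No abstract here</ArticleTitle>
    </Article></MedlineCitation></PubmedArticle></PubmedArticleSet>'
  recs <- parse_medline_xml(xml)
  expect_equal(recs$abstract, "")

  expect_equal(nrow(parse_medline_xml("<PubmedArticleSet/>")), 0L)

  no_id <- '<PubmedArticleSet><PubmedArticle><MedlineCitation>
    <Article><ArticleTitle>orphan</ArticleTitle></Article>
    </MedlineCitation></PubmedArticle></PubmedArticleSet>'
  expect_warning(out <- parse_medline_xml(no_id), "skipped 1")
  expect_equal(nrow(out), 0L)

  expect_error(parse_medline_xml("<unclosed"), class = "ebm_parse_error")
})

test_that("records round-trip through the XML writer", {
  recs <- make_demo_articles()
  path <- withr::local_tempfile(fileext = ".xml")
  write_medline_xml(recs, path)
  back <- parse_medline_xml(path)
  expect_equal(back, recs)
})

test_that("records round-trip through JSONL with labels", {
  corpus <- make_synthetic_corpus(corpus_spec(n_articles = 20, seed = 2))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, path)
  back <- read_corpus_jsonl(path)
  expect_equal(back, corpus)
})

test_that("data features lowercase, drop stopwords, stem and length-filter", {
  f <- data_features("The Running Studies")
  expect_equal(f, c(run = 1L, studi = 1L))

  expect_length(data_features("the of and"), 0L)
  # single-character token excluded by the default min length 2
  expect_false("a" %in% names(data_features("a vitamin b trial", "")))

  combined <- data_features("running", "running studies")
  expect_equal(combined[["run"]], 2L)   # title and abstract concatenated
})

test_that("metadata features tokenize and fold case only, in meta namespace", {
  m <- metadata_features(mesh_terms = "Randomized Controlled Trial")
  expect_setequal(names(m), c("meta:randomized", "meta:controlled",
                              "meta:trial"))
  # no stemming, no stopword removal
  m2 <- metadata_features(mesh_terms = "The Randomized Studies")
  expect_true("meta:the" %in% names(m2))
  expect_true("meta:studies" %in% names(m2))

  # repeated term counts per occurrence
  m3 <- metadata_features(mesh_terms = c("Humans", "Humans"))
  expect_equal(m3[["meta:humans"]], 2L)

  expect_length(metadata_features(), 0L)
})

test_that("a record with no MeSH is still classifiable from data features", {
  rec <- make_article("1", title = "Running studies of trials",
                      abstract = "A randomized evaluation.")
  feats <- vectorize_corpus(rec, scheme = "count")
  expect_gt(ncol(feats$matrix), 0L)
  expect_false(any(startsWith(feats$vocabulary$token, "meta:")))
})

test_that("count vectorization matches a brute-force dense recount", {
  corpus <- make_synthetic_corpus(corpus_spec(n_articles = 20, seed = 9))[1:10, ]
  feats <- vectorize_corpus(corpus, scheme = "count")
  expect_equal(dim(feats$matrix), c(10L, nrow(feats$vocabulary)))
  dense <- as.matrix(feats$matrix)
  for (i in seq_len(nrow(corpus))) {
    recount <- c(data_features(corpus$title[i], corpus$abstract[i]),
                 metadata_features(corpus$mesh_terms[[i]],
                                   corpus$publication_types[[i]]))
    for (tok in names(recount)) {
      expect_equal(unname(dense[i, tok]), as.numeric(recount[[tok]]))
    }
    expect_equal(sum(dense[i, ]), sum(recount))
  }
})

test_that("vocabulary keeps data and meta namespaces disjoint", {
  corpus <- make_synthetic_corpus(corpus_spec(n_articles = 20, seed = 9))
  feats <- vectorize_corpus(corpus)
  is_meta <- startsWith(feats$vocabulary$token, "meta:")
  expect_true(any(is_meta) && any(!is_meta))
  expect_false(any(duplicated(feats$vocabulary$token)))
  # every metadata token lives under the prefix, so no key can denote both
  meta_recount <- metadata_features(corpus$mesh_terms[[1]])
  expect_true(all(startsWith(names(meta_recount), "meta:")))
})

test_that("two token-disjoint records give a block-diagonal pattern", {
  recs <- dplyr::bind_rows(
    make_article("1", title = "alpha bravo"),
    make_article("2", title = "charlie delta"))
  feats <- vectorize_corpus(recs, scheme = "count")
  dense <- as.matrix(feats$matrix)
  expect_true(all(dense[1, dense[2, ] > 0] == 0))
  expect_true(all(dense[2, dense[1, ] > 0] == 0))
})

test_that("single-document corpora degenerate to equal IDF weights", {
  feats <- vectorize_corpus(make_article("1", title = "alpha bravo charlie"))
  expect_equal(length(unique(feats$vocabulary$idf)), 1L)
})

test_that("vectorization is deterministic", {
  corpus <- make_synthetic_corpus(corpus_spec(n_articles = 20, seed = 4))
  a <- vectorize_corpus(corpus)
  b <- vectorize_corpus(corpus)
  expect_identical(a$vocabulary, b$vocabulary)
  expect_equal(a$matrix, b$matrix)
  expect_error(vectorize_corpus(make_demo_articles()[0, ]),
               class = "ebm_validation_error")
})
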