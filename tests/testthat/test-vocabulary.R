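test_that("sentence splitting honors terminal punctuation and abbreviations", {
  expect_identical(splitSentences("A. B? C."), c("A.", "B?", "C."))
  expect_identical(splitSentences("No terminal punctuation here"),
                   "No terminal punctuation here")

  # abbreviation-aware: checked against a hand-segmented fixture
  text <- paste("Catalysts, e.g. platinum, are common.",
                "Smith et al. reported a yield of 3.5 units.",
                "Was this expected?",
                "See Fig. 2 for details.",
                "The result, i.e. the product, was pure.")
  out <- splitSentences(text)
  expect_length(out, 5)
  expect_identical(out[1], "Catalysts, e.g. platinum, are common.")
  expect_identical(out[2], "Smith et al. reported a yield of 3.5 units.")
  expect_identical(out[4], "See Fig. 2 for details.")

  # concatenation modulo whitespace reproduces the input
  squash <- function(x) gsub("[[:space:]]+", "", paste(x, collapse = ""))
  expect_identical(squash(out), squash(text))
})

test_that("term normalization is deterministic, idempotent and merges variants", {
  expect_identical(normalizeTerm("Single-Atom Catalysts"),
                   "single atom catalyst")
  expect_identical(normalizeTerm("alkanes"), "alkane")
  expect_identical(normalizeTerm("thing"), "thing")
  expect_identical(normalizeTerm("Noble Gases"), "noble gas")
  expect_identical(normalizeTerm("matrices"), "matrix")

  forms <- c("Single-Atom Catalyst", "SINGLE ATOM CATALYSTS", "studies",
             "X-ray diffraction", "bases", "gas", "glass", "focus",
             "analysis", "species", "3,5-dimethyl", "alkynes; alkenes")
  once <- normalizeTerm(forms)
  expect_identical(normalizeTerm(once), once)   # idempotence
})

test_that("verification discards terms absent from the source text", {
  sentence <- "The single atom catalyst was supported on carbon."
  fb <- functionBackend(function(req) c("single atom catalyst", "unicorn"))
  out <- extractTerms(sentence, fb)
  expect_identical(as.character(out), "single atom catalyst")
  expect_identical(attr(out, "nRejected"), 1L)

  # hyphenation variant kept under normalized matching
  fb2 <- functionBackend(function(req) "Single-Atom Catalyst")
  expect_identical(as.character(extractTerms(sentence, fb2)),
                   "Single-Atom Catalyst")
  # ... but dropped under raw matching
  expect_length(extractTerms(sentence, fb2, verifyMode = "raw"), 0)

  fb3 <- functionBackend(function(req) character(0))
  expect_length(extractTerms(sentence, fb3), 0)
})

test_that("acronym pairs verify both members against the text", {
  text <- "Single Atom Catalysts (SACs) are studied. DFT was not defined here."
  fb <- functionBackend(function(req) {
    if (req$role == "acronym_extract")
      data.frame(acronym = c("SACs", "DFT", "XYZ"),
                 expansion = c("Single Atom Catalysts",
                               "Density Functional Theory",
                               "Single Atom Catalysts"),
                 stringsAsFactors = FALSE)
    else character(0)
  })
  out <- extractAcronyms(text, fb)
  # DFT's expansion never occurs; XYZ itself never occurs: both dropped
  expect_identical(out$acronym, "SACs")
  expect_identical(out$expansion, "Single Atom Catalysts")
})

test_that("vocabulary merges lemma-equal surface forms across papers", {
  papers <- c(p1 = "We study Single-Atom Catalysts in detail.",
              p2 = "A single atom catalyst has isolated sites.")
  fb <- functionBackend(function(req) {
    switch(req$role,
      term_extract = if (req$payload$paperId == "p1")
        "Single-Atom Catalysts" else "single atom catalyst",
      acronym_extract = data.frame(acronym = character(0),
                                   expansion = character(0)),
      character(0))
  })
  v <- buildVocabulary(papers, fb)
  expect_identical(vocabularyLemmas(v), "single atom catalyst")
  expect_setequal(v@surfaceForms[["single atom catalyst"]],
                  c("Single-Atom Catalysts", "single atom catalyst"))
  # canonical surface form = earliest seen in corpus order
  expect_identical(v@entries$canonical, "Single-Atom Catalysts")
  expect_setequal(v@papers[["single atom catalyst"]], c("p1", "p2"))

  # merge idempotence: a second run yields the identical vocabulary
  v2 <- buildVocabulary(papers, fb)
  expect_identical(v@entries, v2@entries)
  expect_identical(v@surfaceForms, v2@surfaceForms)

  expect_error(buildVocabulary(list(), fb), "empty corpus")
})

test_that("acronyms attach as aliases, not independent entries", {
  papers <- c(p1 = "Single Atom Catalysts (SACs) are small. SACs work well.")
  fb <- functionBackend(function(req) {
    switch(req$role,
      term_extract = c("Single Atom Catalysts", "SACs"),
      acronym_extract = data.frame(acronym = "SACs",
                                   expansion = "Single Atom Catalysts",
                                   stringsAsFactors = FALSE),
      character(0))
  })
  v <- buildVocabulary(papers, fb)
  expect_identical(vocabularyLemmas(v), "single atom catalyst")
  expect_identical(resolveAlias(v, "sac"), "single atom catalyst")
  expect_identical(resolveAlias(v, "other term"), "other term")
  expect_identical(v@aliases[["single atom catalyst"]], "SACs")
})

test_that("no fabricated surface form survives an adversarial backend", {
  set.seed(31)
  w <- generatePlantedWorld(plantedSpec(depth = 3, nTerms = 20, nPapers = 8,
                                        coverage = 1, seed = 13))
  papers <- plantedCorpus(w)
  honest <- plantedBackend(w, 0, 0)
  adversary <- functionBackend(function(req) {
    real <- generate(honest, req)
    if (req$role != "term_extract") return(real)
    junk <- replicate(max(1L, length(real)),
                      paste0("zz", paste(sample(letters, 7), collapse = "")))
    c(real, junk)   # ~50% fabricated
  })
  v <- buildVocabulary(papers, adversary)
  all_surfaces <- unlist(v@surfaceForms)
  for (s in all_surfaces) {
    hit <- any(vapply(papers, function(p) verifySurface(s, p), TRUE))
    expect_true(hit, label = paste("surface verified in corpus:", s))
  }
  expect_false(any(grepl("^zz", all_surfaces)))
})

test_that("pipeline also runs with sentence splitting disabled", {
  w <- generatePlantedWorld(plantedSpec(depth = 3, nTerms = 15, nPapers = 4,
                                        coverage = 1, seed = 17))
  b <- plantedBackend(w, 0, 0)
  v <- buildVocabulary(plantedCorpus(w), b, splitIntoSentences = FALSE)
  expect_true(all(w$vocabLemmas %in% vocabularyLemmas(v)))
  # one term-extraction call per paper in whole-text mode
  expect_identical(unname(ledgerCounts(b)["term_extract"]),
                   length(w$papers))
})
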