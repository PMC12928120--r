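test_that("leaves instantiate the KG; non-leaves are classes", {
  chain <- tx("a>thing", "b>a")
  out <- instantiateKG(chain)
  expect_identical(kgInstances(out$kg), "b")
  expect_identical(out$schema@classes, "a")   # root is a class, kept apart
  expect_identical(out$kg@instanceOf,
                   data.frame(instance = "b", class = "a"))

  # an ontology with four classes (root included) whose three leaf children
  # carry one instance each: three instances, three instance-of links
  ex <- tx("metal>thing", "support>thing", "catalyst>thing",
           "pt atom>metal", "carbon>support", "pt on carbon>catalyst")
  ex_out <- instantiateKG(ex)
  expect_length(c(taxonomyRoot(ex), ex_out$schema@classes), 4)
  expect_length(kgInstances(ex_out$kg), 3)
  expect_identical(nrow(kgInstanceOf(ex_out$kg)), 3L)

  # a multi-parent leaf instantiates both parents
  diamond <- tx("a>thing", "b>thing", "c>a", "c>b")
  dd <- instantiateKG(diamond)
  expect_identical(kgInstanceOf(dd$kg),
                   data.frame(instance = c("c", "c"), class = c("a", "b")))

  expect_error(instantiateKG(Taxonomy()), "non-root")
})

test_that("leaf/instance duality holds on random taxonomies", {
  set.seed(7)
  for (i in 1:25) {
    rt <- random_taxonomy(sample(3:10, 1))
    kg <- instantiateKG(rt)$kg
    expect_setequal(kgInstances(kg), taxonomyLeaves(rt))
  }
})

test_that("relation extraction filters to the vocabulary and resolves aliases", {
  papers <- c(p1 = paste("Pt single atoms (PSAs) are anchored.",
                         "The nitrogen doped carbon is a support."))
  vb <- functionBackend(function(req) {
    switch(req$role,
      term_extract = c("Pt single atoms", "nitrogen doped carbon"),
      acronym_extract = data.frame(acronym = "PSAs",
                                   expansion = "Pt single atoms",
                                   stringsAsFactors = FALSE),
      character(0))
  })
  vocab <- buildVocabulary(papers, vb)

  tb <- functionBackend(function(req)
    data.frame(subject = c("PSAs", "Pt single atoms", "Pt single atoms"),
               predicate = c("Supported  On", "supported on", "measured by"),
               object = c("nitrogen doped carbon", "nitrogen-doped carbon",
                          "Dr. Smith"),
               stringsAsFactors = FALSE))
  out <- extractRelations(papers[[1]], vocab, tb, m = 1, paperId = "p1")
  # acronym subject resolves to the expansion; predicate normalizes;
  # duplicates collapse; the non-vocabulary triple is dropped
  expect_identical(out$subject, "pt single atom")
  expect_identical(out$predicate, "supported on")
  expect_identical(out$object, "nitrogen doped carbon")
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "nDropped"), 1L)

  empty_vocab <- new("Vocabulary",
                     entries = data.frame(lemma = character(0),
                                          canonical = character(0)),
                     surfaceForms = list(), aliases = list(),
                     aliasTo = character(0), papers = list(),
                     perPaper = list())
  expect_identical(nrow(extractRelations(papers[[1]], empty_vocab, tb)), 0L)
})

test_that("relation endpoints stay inside the vocabulary under adversarial noise", {
  w <- generatePlantedWorld(plantedSpec(depth = 3, nTerms = 15, nPapers = 4,
                                        coverage = 1, seed = 41))
  b <- plantedBackend(w, 0, 0)
  vocab <- buildVocabulary(plantedCorpus(w), b)
  honest <- plantedBackend(w, 0, 0)
  adversary <- functionBackend(function(req) {
    real <- generate(honest, req)
    if (req$role != "triple_extract") return(real)
    rbind(real, data.frame(subject = c("made up subject", real$object[1]),
                           predicate = c("imagined", "studied by"),
                           object = c(real$subject[1] %||% "x",
                                      "professor nobody"),
                           stringsAsFactors = FALSE))
  })
  kg <- instantiateKG(w$taxonomy)$kg
  kg <- extractCorpusRelations(plantedCorpus(w), kg, vocab, adversary, m = 3)
  rel <- kgRelations(kg)
  expect_true(all(rel$subject %in% vocabularyLemmas(vocab)))
  expect_true(all(rel$object %in% vocabularyLemmas(vocab)))
  expect_false(any(rel$predicate %in% c("imagined", "studied by")))
})

test_that("merging KG and ontology is additive on disjoint edge sets", {
  txo <- tx("a>thing", "b>a", "c>a")
  kg <- instantiateKG(txo)$kg
  kg@relations <- data.frame(subject = c("b", "c"),
                             predicate = c("supported on", "bound to"),
                             object = c("c", "b"), stringsAsFactors = FALSE)
  merged <- mergeKgOntology(kg, txo)
  expect_identical(nrow(merged), nrow(kgRelations(kg)) + 3L)
  expect_setequal(unique(merged$edge_type), c("relation", "isA"))

  # empty KG: merged graph is the taxonomy as a labeled graph
  kg0 <- instantiateKG(txo)$kg
  m0 <- mergeKgOntology(kg0, txo)
  expect_identical(nrow(m0), 3L)
  expect_true(all(m0$predicate == "isA"))

  # N-Triples round trip preserves the edge multiset
  nt <- tempfile(fileext = ".nt")
  writeNTriples(merged, nt)
  back <- readNTriples(nt)
  expect_setequal(paste(back$from, back$predicate, back$to),
                  paste(merged$from, merged$predicate, merged$to))
})
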