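small_world <- function(seed = 3) {
  generatePlantedWorld(plantedSpec(depth = 3, nTerms = 15, nPapers = 4,
                                   coverage = 1, seed = seed))
}

test_that("scripted backend replays recorded answers exactly", {
  req <- generationRequest("term_extract", list(text = "x", paperId = "p1"))
  sb <- scriptedBackend(setNames(list(c("alkane", "alkyne")),
                                 requestDigest(req)))
  expect_identical(generate(sb, req), c("alkane", "alkyne"))
  other <- generationRequest("term_extract", list(text = "y", paperId = "p1"))
  expect_identical(generate(sb, other), character(0))
})

test_that("scripted fixtures load from YAML", {
  req <- generationRequest("category_generate", list(paperIds = "p1"))
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(paste0("'", requestDigest(req), "':"),
               "  - metal", "  - ligand"), yml)
  sb <- readScriptedBackend(yml)
  expect_identical(unlist(generate(sb, req)), c("metal", "ligand"))
})

test_that("noise-free planted backend is an exact oracle for isA queries", {
  w <- small_world()
  b <- plantedBackend(w, omissionRate = 0, hallucinationRate = 0)
  pid <- names(w$papers)[[1]]
  facts <- w$papers[[pid]]$isaFacts
  req <- generationRequest("relationship_query",
    list(paperId = pid, taxonomyTerms = taxonomyNodes(w$taxonomy),
         vocab = w$vocabLemmas))
  ans <- generate(b, req)
  expect_setequal(paste(ans$parent, ans$child),
                  paste(facts$parent, facts$child))
})

test_that("planted responses are reproducible and seed-sensitive", {
  w <- small_world()
  b1 <- plantedBackend(w, 0.5, 0.2, seed = 9)
  b2 <- plantedBackend(w, 0.5, 0.2, seed = 9)
  pid <- names(w$papers)[[1]]
  reqs <- lapply(1:10, function(i)
    generationRequest("relationship_query",
      list(paperId = pid, taxonomyTerms = taxonomyNodes(w$taxonomy),
           vocab = w$vocabLemmas), sampleIndex = i))
  s1 <- lapply(reqs, generate, backend = b1)
  s2 <- lapply(reqs, generate, backend = b2)
  expect_identical(s1, s2)
  b3 <- plantedBackend(w, 0.5, 0.2, seed = 10)
  s3 <- lapply(reqs, generate, backend = b3)
  expect_false(identical(s1, s3))
})

test_that("omission noise retains true facts at the configured rate", {
  w <- generatePlantedWorld(plantedSpec(depth = 2, nTerms = 4, nPapers = 1,
                                        coverage = 1, seed = 5))
  pid <- names(w$papers)[[1]]
  facts <- w$papers[[pid]]$isaFacts
  expect_gte(nrow(facts), 1L)
  target <- paste(facts$parent[1], facts$child[1])
  b <- plantedBackend(w, omissionRate = 0.3, hallucinationRate = 0, seed = 2)
  hits <- vapply(1:2000, function(i) {
    ans <- generate(b, generationRequest("relationship_query",
      list(paperId = pid, taxonomyTerms = taxonomyNodes(w$taxonomy),
           vocab = w$vocabLemmas), sampleIndex = i))
    target %in% paste(ans$parent, ans$child)
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.70), 0.02)
})

test_that("self-consistency keeps strict-majority items only", {
  responses <- list(c("a", "b"), c("a"), c("c"))
  fb <- functionBackend(function(req) responses[[req$sampleIndex]])
  out <- selfConsistent(fb, generationRequest("term_extract"), m = 3)
  expect_identical(as.character(out), "a")   # 2/3 kept; b, c (1/3) dropped

  # unanimity: output equals any sample
  fb2 <- functionBackend(function(req) c("x", "y"))
  out2 <- selfConsistent(fb2, generationRequest("term_extract"), m = 5)
  expect_setequal(as.character(out2), c("x", "y"))

  expect_error(selfConsistent(fb, generationRequest("term_extract"), m = 4),
               class = "ontokit_config_error")
  expect_error(selfConsistent(fb, generationRequest("term_extract"), m = 0),
               class = "ontokit_config_error")
})

test_that("majority-vote survival follows the binomial closed form", {
  # per-sample retention p: item kept iff present in > m/2 samples, so the
  # survival probability is P(Bin(m, p) >= ceiling((m+1)/2))
  survival_sim <- function(p, m, trials = 400) {
    mean(vapply(seq_len(trials), function(t) {
      fb <- functionBackend(function(req) {
        set.seed(t * 1000 + req$sampleIndex)
        if (stats::runif(1) < p) "item" else character(0)
      })
      "item" %in% selfConsistent(fb, generationRequest("term_extract"), m = m)
    }, TRUE))
  }
  closed <- function(p, m) stats::pbinom(floor(m / 2), m, p,
                                         lower.tail = FALSE)
  sims <- vapply(c(1, 3, 5, 7, 9), survival_sim, 0, p = 0.7)
  expect_true(all(abs(sims - closed(0.7, c(1, 3, 5, 7, 9))) < 0.08))
  # monotone increasing in m when p > 0.5 (closed form is exact)
  expect_true(all(diff(closed(0.7, c(1, 3, 5, 7, 9))) > 0))
  # monotone decreasing when p < 0.5, vanishing with m
  expect_true(all(diff(closed(0.3, c(1, 3, 5, 7, 9))) < 0))
  expect_lt(closed(0.3, 9), 0.11)
})

test_that("the call ledger records every backend invocation", {
  fb <- functionBackend(function(req) character(0))
  for (i in 1:3)
    generate(fb, generationRequest("term_extract", list(text = "abc")))
  selfConsistent(fb, generationRequest("relationship_query"), m = 5)
  counts <- ledgerCounts(fb)
  expect_identical(unname(counts["term_extract"]), 3L)
  expect_identical(unname(counts["relationship_query"]), 5L)
  tab <- ledgerTable(fb)
  expect_identical(nrow(tab), 8L)
  expect_true(all(tab$payload_chars[tab$role == "term_extract"] == 3L))
  resetLedger(fb)
  expect_identical(nrow(ledgerTable(fb)), 0L)
})
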