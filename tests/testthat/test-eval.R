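test_that("path matching maximizes shared nodes with deterministic ties", {
  gt <- tx("a>thing", "b>a", "c>b")
  gt_path <- c("thing", "a", "b", "c")

  expect_null(matchPath(gt_path, tx("x>thing")))           # endpoint absent
  expect_identical(matchPath(gt_path, gt), gt_path)        # identity

  # diamond: the branch sharing 2 nodes beats the branch sharing 1
  rec <- tx("a>thing", "x>thing", "c>a", "c>x")
  expect_identical(matchPath(gt_path, rec), c("thing", "a", "c"))
})

test_that("hierarchical metrics match hand-enumerated values", {
  gt <- tx("a>thing", "b>a", "c>b")
  expect_equal(hierarchicalMetrics(gt, gt),
               list(hP = 1, hR = 1, hF1 = 1, hAcc = 1, nPaths = 3L,
                    nMatched = 3L))

  # root-only reconstruction: recall and accuracy vanish; precision is
  # reported as 0 with zero matched paths
  h0 <- hierarchicalMetrics(gt, Taxonomy())
  expect_identical(h0[c("hP", "hR", "hF1", "hAcc")],
                   list(hP = 0, hR = 0, hF1 = 0, hAcc = 0))
  expect_identical(h0$nMatched, 0L)

  # gt chain thing>a>b>c vs reconstruction {thing>a, a>c}: the c-path has
  # gt nodes {a,b,c}, matched {a,c}, shared {a,c}: recall 2/3, precision 1
  rec <- tx("a>thing", "c>a")
  h <- hierarchicalMetrics(gt, rec)
  expect_equal(h$hR, mean(c(1, 0, 2 / 3)))   # paths to a, b (unmatched), c
  expect_equal(h$hP, 1)
  expect_equal(h$hAcc, 2 / 3)
  expect_equal(h$hF1, 2 * h$hP * h$hR / (h$hP + h$hR))

  expect_error(hierarchicalMetrics(gt, Taxonomy(root = "entity")), "root")
})

test_that("ancestor error count averages per-path symmetric discrepancies", {
  gt <- tx("a>thing", "b>a", "c>b")
  expect_identical(ancestorErrorCount(gt, gt), 0)

  # chain example: paths to a, b, c contribute 0, 2 (b unmatched, full
  # node-set size), and 1 (symmetric difference {b})
  rec <- tx("a>thing", "c>a")
  expect_equal(ancestorErrorCount(gt, rec), mean(c(0, 2, 1)))

  # root-only reconstruction with gt path sizes {1, 2, 3}: AEC = 2
  expect_equal(ancestorErrorCount(gt, Taxonomy()), 2)

  # one-sided mode counts only missing ground-truth nodes: c's path gains x
  # (penalized symmetrically) and loses b (penalized in both modes)
  rec2 <- tx("a>thing", "x>a", "c>x")
  expect_equal(ancestorErrorCount(gt, rec2,
                                  metricOptions(aecMode = "missing")),
               mean(c(0, 2, 1)))
  expect_equal(ancestorErrorCount(gt, rec2), mean(c(0, 2, 2)))
})

test_that("LCA preservation uses the DAG LCA-set intersection criterion", {
  gt <- tx("a>thing", "b>a", "c>b")
  expect_identical(lcaPreservation(gt, gt), 1)

  # siblings under the root re-parented: gt LCA {thing} vs rec LCA {a}
  sib <- tx("a>thing", "b>thing")
  nest <- tx("a>thing", "b>a")
  expect_identical(lcaPreservation(sib, nest), 0)

  # a missing node spoils every pair it participates in
  gt2 <- tx("a>thing", "b>thing", "c>a")
  rec2 <- tx("a>thing", "c>a")   # b absent: pairs (a,b), (b,c) fail
  expect_equal(lcaPreservation(gt2, rec2), 1 / 3)
})

test_that("set accuracies count term, leaf and instance overlap", {
  gt <- tx("a>thing", "b>a", "c>a", "d>b")
  expect_identical(setAccuracies(gt, gt),
                   list(termAccuracy = 1, leafAccuracy = 1, kgAccuracy = 1))

  rec <- tx("a>thing", "b>a", "c>a")   # misses 1 of 4 terms
  expect_equal(setAccuracies(gt, rec)$termAccuracy, 0.75)

  # a gt instance present in the reconstruction as a non-leaf counts for
  # term accuracy but not for KG accuracy (6-node fixture)
  gt6 <- tx("a>thing", "b>a", "c>a", "d>b", "e>b")
  rec6 <- tx("a>thing", "b>a", "c>a", "d>b", "e>d")  # d now internal
  a6 <- setAccuracies(gt6, rec6,
                      gtKG = instantiateKG(gt6)$kg,
                      recKG = instantiateKG(rec6)$kg)
  expect_equal(a6$termAccuracy, 1)
  expect_equal(a6$kgAccuracy, 2 / 3)   # of gt instances {c,d,e}, d is internal
})

test_that("every metric agrees with the brute-force oracle on random DAG pairs", {
  set.seed(101)
  for (i in 1:60) {
    gt <- random_taxonomy(sample(4:12, 1), multiparent = 0.3)
    rec <- random_taxonomy(sample(4:12, 1), multiparent = 0.3)
    got <- evaluateOntology(gt, rec)
    want <- oracle_metrics(taxonomyEdges(gt), taxonomyEdges(rec))
    for (metric in names(want)) {
      expect_equal(got[[metric]], want[[metric]], tolerance = 1e-9,
                   label = sprintf("%s (case %d)", metric, i))
    }
  }
})

test_that("deleting a correct edge from a tree never increases recall", {
  set.seed(55)
  for (i in 1:25) {
    gt <- random_taxonomy(sample(4:10, 1), multiparent = 0)
    base <- hierarchicalMetrics(gt, gt)$hR
    e <- taxonomyEdges(gt)
    drop <- sample(nrow(e), 1)
    # removing one tree edge detaches a subtree; rebuild the reconstruction
    # from the surviving edges that remain root-reachable
    keep <- e[-drop, , drop = FALSE]
    reach <- "thing"
    repeat {
      add <- keep$child[keep$parent %in% reach & !(keep$child %in% reach)]
      if (!length(add)) break
      reach <- c(reach, add)
    }
    keep <- keep[keep$parent %in% reach, , drop = FALSE]
    rec <- Taxonomy(keep)
    expect_lte(hierarchicalMetrics(gt, rec)$hR, base)
  }
})

test_that("metric report prints all suite rows and serializes to JSON", {
  gt <- tx("a>thing", "b>a")
  rep <- evaluateOntology(gt, gt)
  txt <- capture.output(print(rep))
  expect_true(any(grepl("Hierarchical F1", txt)))
  expect_true(any(grepl("KG accuracy", txt)))
  jf <- tempfile(fileext = ".json")
  writeMetricsJSON(rep, jf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$hF1, 1)
  expect_equal(back$AEC, 0)
})
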