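## Taxonomy-reconstruction metric suite, generalized to DAGs. The unit of
## every hierarchical metric is the root-to-node path: a DAG node reachable
## through several parents contributes one ground-truth path per route, and
## each ground-truth path is compared against the most similar reconstructed
## path ending at the same (lemma-identical) node.

#' Options for the hierarchical metric suite
#'
#' The concrete metric forms admit a few readings; all are exposed here so
#' alternatives are testable. Defaults: the root is excluded from every
#' path node set, the endpoint is included, a ground-truth path whose
#' endpoint is absent from the reconstruction contributes 0 to recall, and
#' precision is macro-averaged over matched paths only (set
#' \code{precisionAveraging = "micro"} for a pooled numerator/denominator).
#'
#' @param rootExcluded exclude the root from path node sets.
#' @param includeEndpoint include the path endpoint in its node set.
#' @param noMatchZero unmatched ground-truth paths contribute 0 to recall.
#' @param precisionAveraging \code{"matched"} (macro over matched paths) or
#'   \code{"micro"}.
#' @param aecMode \code{"symmetric"} (size of the symmetric difference) or
#'   \code{"missing"} (ground-truth nodes absent from the matched path
#'   only).
#' @return list of options.
#' @export
metricOptions <- function(rootExcluded = TRUE, includeEndpoint = TRUE,
                          noMatchZero = TRUE,
                          precisionAveraging = c("matched", "micro"),
                          aecMode = c("symmetric", "missing")) {
  list(rootExcluded = rootExcluded,
       includeEndpoint = includeEndpoint,
       noMatchZero = noMatchZero,
       precisionAveraging = match.arg(precisionAveraging),
       aecMode = match.arg(aecMode))
}

.pathNodeSet <- function(path, opts) {
  nodes <- path
  if (opts$rootExcluded) nodes <- nodes[-1L]
  if (!opts$includeEndpoint && length(nodes)) nodes <- nodes[-length(nodes)]
  unique(nodes)
}

#' Match a ground-truth path to its most similar reconstructed path
#'
#' Among all reconstructed root-paths ending at the same lemma key as
#' \code{gtPath}'s endpoint, returns the one sharing the most nodes with
#' the ground-truth path; ties break deterministically by shortest path,
#' then lexicographic node sequence. No-match (NULL) iff the endpoint is
#' absent from the reconstruction.
#'
#' @param gtPath character vector, a root-to-node path in the ground truth.
#' @param reconstructed the reconstructed \linkS4class{Taxonomy}.
#' @param opts see \code{\link{metricOptions}}.
#' @return the matched path (character vector) or \code{NULL}.
#' @export
matchPath <- function(gtPath, reconstructed, opts = metricOptions()) {
  endpoint <- gtPath[length(gtPath)]
  if (!(endpoint %in% reconstructed@nodes)) return(NULL)
  candidates <- enumerateRootPaths(reconstructed, endpoint)
  gtSet <- .pathNodeSet(gtPath, opts)
  shared <- vapply(candidates, function(p)
    length(intersect(.pathNodeSet(p, opts), gtSet)), 0L)
  lens <- lengths(candidates)
  keys <- vapply(candidates, paste, "", collapse = "␟")
  best <- order(-shared, lens, keys)[1L]
  candidates[[best]]
}

## shared per-path bookkeeping for all hierarchical metrics
.pathComparisons <- function(groundTruth, reconstructed, opts) {
  if (groundTruth@root != reconstructed@root)
    stop("ground truth and reconstruction must share the same root (",
         groundTruth@root, " vs ", reconstructed@root, ")")
  gtPaths <- unlist(.allRootPaths(groundTruth), recursive = FALSE,
                    use.names = FALSE)
  lapply(gtPaths, function(p) {
    gtSet <- .pathNodeSet(p, opts)
    m <- matchPath(p, reconstructed, opts)
    if (is.null(m)) {
      list(gtSet = gtSet, matched = FALSE, matchSet = character(0),
           shared = character(0))
    } else {
      ms <- .pathNodeSet(m, opts)
      list(gtSet = gtSet, matched = TRUE, matchSet = ms,
           shared = intersect(gtSet, ms))
    }
  })
}

#' Hierarchical precision, recall, F1 and accuracy over DAG taxonomies
#'
#' For every ground-truth root-path, the most similar reconstructed path
#' ending at the same node is found (\code{\link{matchPath}}). Hierarchical
#' recall averages |shared nodes| / |ground-truth path nodes| over all
#' ground-truth paths (unmatched paths contribute 0); hierarchical
#' precision averages |shared nodes| / |matched path nodes| over matched
#' paths only; hF1 is their harmonic mean (0 when both are 0); hierarchical
#' accuracy is the fraction of ground-truth paths whose matched path shares
#' at least one node. Path node sets exclude the root and include the
#' endpoint (configurable).
#'
#' @param groundTruth,reconstructed \linkS4class{Taxonomy} objects sharing
#'   the same root.
#' @param opts see \code{\link{metricOptions}}.
#' @return list with \code{hP}, \code{hR}, \code{hF1}, \code{hAcc},
#'   \code{nPaths}, \code{nMatched}.
#' @export
hierarchicalMetrics <- function(groundTruth, reconstructed,
                                opts = metricOptions()) {
  cmp <- .pathComparisons(groundTruth, reconstructed, opts)
  n <- length(cmp)
  if (n == 0L)
    return(list(hP = 1, hR = 1, hF1 = 1, hAcc = 1, nPaths = 0L,
                nMatched = 0L))
  recall <- vapply(cmp, function(x) {
    if (!x$matched && opts$noMatchZero) return(0)
    if (!length(x$gtSet)) return(1)
    length(x$shared) / length(x$gtSet)
  }, 0)
  matched <- Filter(function(x) x$matched, cmp)
  hP <- if (!length(matched)) 0
  else if (opts$precisionAveraging == "micro") {
    num <- sum(vapply(matched, function(x) length(x$shared), 0L))
    den <- sum(vapply(matched, function(x) length(x$matchSet), 0L))
    if (den == 0L) 0 else num / den
  } else {
    mean(vapply(matched, function(x) {
      if (!length(x$matchSet)) return(1)
      length(x$shared) / length(x$matchSet)
    }, 0))
  }
  hR <- mean(recall)
  hAcc <- mean(vapply(cmp, function(x)
    as.numeric(x$matched && length(x$shared) >= 1L), 0))
  hF1 <- if (hP + hR == 0) 0 else 2 * hP * hR / (hP + hR)
  list(hP = hP, hR = hR, hF1 = hF1, hAcc = hAcc,
       nPaths = n, nMatched = length(matched))
}

#' Ancestor Error Count
#'
#' For each ground-truth root-path, the discrepancy is the size of the
#' symmetric difference between its (root-excluded) node set and the node
#' set of its most similar reconstructed path; an unmatched path counts its
#' full node-set size. AEC is the mean discrepancy over all ground-truth
#' paths (0 for a perfect reconstruction). \code{aecMode = "missing"}
#' counts only ground-truth nodes missing from the matched path.
#'
#' @inheritParams hierarchicalMetrics
#' @return non-negative number.
#' @export
ancestorErrorCount <- function(groundTruth, reconstructed,
                               opts = metricOptions()) {
  cmp <- .pathComparisons(groundTruth, reconstructed, opts)
  if (!length(cmp)) return(0)
  disc <- vapply(cmp, function(x) {
    if (!x$matched) return(length(x$gtSet))
    miss <- length(setdiff(x$gtSet, x$matchSet))
    if (opts$aecMode == "missing") miss
    else miss + length(setdiff(x$matchSet, x$gtSet))
  }, 0)
  mean(disc)
}

## reflexive ancestor sets for every node: node -> character vector
.ancestorSets <- function(taxonomy) {
  g <- taxonomyToIgraph(taxonomy)  # edges parent -> child
  stats::setNames(lapply(taxonomy@nodes, function(n)
    igraph::subcomponent(g, n, mode = "in")$name), taxonomy@nodes)
}

## the LCA *set* of a pair in a DAG: common (reflexive) ancestors none of
## whose proper descendants are also common ancestors
.lcaSet <- function(a, b, anc) {
  ca <- intersect(anc[[a]], anc[[b]])
  if (!length(ca)) return(character(0))
  keep <- vapply(ca, function(c0) {
    !any(vapply(setdiff(ca, c0), function(d) c0 %in% anc[[d]], TRUE))
  }, TRUE)
  ca[keep]
}

#' Lowest-common-ancestor preservation
#'
#' Over all unordered pairs of distinct non-root ground-truth nodes: a pair
#' is preserved iff both nodes exist in the reconstruction and the
#' ground-truth LCA set intersects the reconstructed LCA set. In a DAG the
#' \dQuote{lowest common ancestor} is a set (the common ancestors with no
#' common-ancestor proper descendant); non-empty intersection is the
#' preservation criterion. Ancestor sets are reflexive, so for nested
#' nodes the deeper node itself can be the LCA.
#'
#' @inheritParams hierarchicalMetrics
#' @return preserved fraction in [0, 1] (1 when fewer than 2 non-root
#'   ground-truth nodes exist).
#' @export
lcaPreservation <- function(groundTruth, reconstructed,
                            opts = metricOptions()) {
  if (groundTruth@root != reconstructed@root)
    stop("ground truth and reconstruction must share the same root")
  nodes <- sort(setdiff(groundTruth@nodes, groundTruth@root))
  if (length(nodes) < 2L) return(1)
  ancGT <- .ancestorSets(groundTruth)
  ancRec <- .ancestorSets(reconstructed)
  pairs <- utils::combn(nodes, 2L)
  ok <- vapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    if (!(a %in% reconstructed@nodes) || !(b %in% reconstructed@nodes))
      return(FALSE)
    length(intersect(.lcaSet(a, b, ancGT), .lcaSet(a, b, ancRec))) > 0L
  }, TRUE)
  mean(ok)
}

#' Term, leaf and KG set accuracies
#'
#' Plain set-overlap metrics: term accuracy is the fraction of ground-truth
#' (non-root) terms present in the reconstruction; leaf accuracy the same
#' over leaves; KG accuracy the fraction of ground-truth KG instances that
#' are also instances (leaves) of the reconstruction. A ground-truth
#' instance present in the reconstruction as a non-leaf counts toward term
#' accuracy but not toward leaf/KG accuracy.
#'
#' @param groundTruth,reconstructed \linkS4class{Taxonomy} objects.
#' @param gtKG,recKG optional \linkS4class{KnowledgeGraph}s; when omitted,
#'   instances default to taxonomy leaves.
#' @return list with \code{termAccuracy}, \code{leafAccuracy},
#'   \code{kgAccuracy}.
#' @export
setAccuracies <- function(groundTruth, reconstructed,
                          gtKG = NULL, recKG = NULL) {
  gtTerms <- setdiff(groundTruth@nodes, groundTruth@root)
  recTerms <- setdiff(reconstructed@nodes, reconstructed@root)
  frac <- function(gt, rec) {
    if (!length(gt)) return(1)
    length(intersect(gt, rec)) / length(gt)
  }
  gtInst <- if (is.null(gtKG)) taxonomyLeaves(groundTruth) else gtKG@instances
  recInst <- if (is.null(recKG)) taxonomyLeaves(reconstructed)
             else recKG@instances
  list(termAccuracy = frac(gtTerms, recTerms),
       leafAccuracy = frac(taxonomyLeaves(groundTruth),
                           taxonomyLeaves(reconstructed)),
       kgAccuracy = frac(gtInst, recInst))
}

#' Full metrics report for a reconstructed ontology
#'
#' Computes the complete suite: term/leaf/KG accuracy, hierarchical
#' precision/recall/F1/accuracy, ancestor error count and LCA preservation.
#'
#' @inheritParams setAccuracies
#' @param opts see \code{\link{metricOptions}}.
#' @return a \code{MetricsReport} (classed list) with fields
#'   \code{term_accuracy}, \code{hP}, \code{hR}, \code{hF1}, \code{hAcc},
#'   \code{AEC}, \code{LCA}, \code{leaf_accuracy}, \code{kg_accuracy},
#'   \code{n_paths}, \code{n_matched}.
#' @export
evaluateOntology <- function(groundTruth, reconstructed,
                             gtKG = NULL, recKG = NULL,
                             opts = metricOptions()) {
  h <- hierarchicalMetrics(groundTruth, reconstructed, opts)
  acc <- setAccuracies(groundTruth, reconstructed, gtKG, recKG)
  structure(list(
    term_accuracy = acc$termAccuracy,
    hP = h$hP, hR = h$hR, hF1 = h$hF1, hAcc = h$hAcc,
    AEC = ancestorErrorCount(groundTruth, reconstructed, opts),
    LCA = lcaPreservation(groundTruth, reconstructed, opts),
    leaf_accuracy = acc$leafAccuracy,
    kg_accuracy = acc$kgAccuracy,
    n_paths = h$nPaths, n_matched = h$nMatched),
    class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  rows <- c("Term accuracy" = "term_accuracy",
            "Hierarchical precision (hP)" = "hP",
            "Hierarchical recall (hR)" = "hR",
            "Hierarchical F1 (hF1)" = "hF1",
            "Hierarchical accuracy (hAcc)" = "hAcc",
            "Ancestor error count (AEC)" = "AEC",
            "LCA preservation" = "LCA",
            "Leaf accuracy" = "leaf_accuracy",
            "KG accuracy" = "kg_accuracy")
  cat("Ontology reconstruction metrics",
      sprintf("(%d ground-truth paths, %d matched)\n",
              x$n_paths, x$n_matched))
  for (nm in names(rows)) {
    cat(sprintf("  %-29s %8.4f\n", nm, x[[rows[nm]]]))
  }
  invisible(x)
}

#' @rdname evaluateOntology
#' @param x a \code{MetricsReport}.
#' @param path output file.
#' @export
writeMetricsJSON <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
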