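## Stage 3: incremental, cycle-guarded construction of the global isA
## taxonomy. Starting from the root and the curated categories, the builder
## makes K full passes over the corpus; each pass asks the backend, per
## paper, which vocabulary terms t sit under which existing taxonomy terms s
## and inserts the accepted (child = t, parent = s) edges unless they would
## create a cycle. A term whose parent is not yet placed simply waits for a
## later pass.

#' Query isA placements for one paper
#'
#' Asks the backend for (s, t) pairs — s an existing taxonomy term, t a term
#' of this paper's vocabulary — under self-consistency, then enforces the
#' contract: pairs whose parent is not a taxonomy node or whose child is not
#' in the paper vocabulary are filtered out (counts attached as
#' attributes). Backend failures yield an empty set with a warning so the
#' iteration continues.
#'
#' @param paperText text of the paper.
#' @param taxonomy current \linkS4class{Taxonomy}.
#' @param vocab character vector of the paper's vocabulary lemma keys (V_i).
#' @param backend a \linkS4class{GenerationBackend}.
#' @param m odd self-consistency sample count.
#' @param paperId paper id forwarded in the payload.
#' @param seed request seed.
#' @return data.frame with columns \code{parent} (s), \code{child} (t);
#'   attributes \code{nRejectedUnknownParent}, \code{nRejectedNotInVocab}.
#' @export
queryRelationships <- function(paperText, taxonomy, vocab, backend, m = 3L,
                               paperId = "paper", seed = 0L) {
  if (!length(vocab)) {
    out <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "nRejectedUnknownParent") <- 0L
    attr(out, "nRejectedNotInVocab") <- 0L
    return(out)
  }
  req <- generationRequest(
    "relationship_query",
    list(text = paperText, paperId = paperId,
         taxonomyTerms = taxonomyNodes(taxonomy), vocab = vocab),
    seed = seed)
  pairs <- tryCatch(selfConsistent(backend, req, m = m),
    ontokit_config_error = function(e) stop(e),
    error = function(e) {
      warning("relationship query failed for paper '", paperId, "': ",
              conditionMessage(e))
      NULL
    })
  empty <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(pairs) || !is.data.frame(pairs) || !nrow(pairs)) {
    attr(empty, "nRejectedUnknownParent") <- 0L
    attr(empty, "nRejectedNotInVocab") <- 0L
    return(empty)
  }
  names(pairs)[1:2] <- c("parent", "child")
  pairs <- unique(pairs[, c("parent", "child"), drop = FALSE])
  okParent <- pairs$parent %in% taxonomy@nodes
  okVocab <- pairs$child %in% vocab
  out <- pairs[okParent & okVocab, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nRejectedUnknownParent") <- sum(!okParent)
  attr(out, "nRejectedNotInVocab") <- sum(okParent & !okVocab)
  out
}

## canonical insertion order within one paper's accepted pair set:
## pairs whose parent is already a node first, then lexicographic
.canonicalPairOrder <- function(pairs, taxonomy) {
  present <- pairs$parent %in% taxonomy@nodes
  pairs[order(!present, pairs$parent, pairs$child), , drop = FALSE]
}

#' Build the taxonomy by iterative placement (K passes over the corpus)
#'
#' Starts from the root with the curated categories as its direct children
#' and performs \code{K} full passes over the corpus. For each paper the
#' backend proposes (parent, child) placements under self-consistency; a
#' pair is inserted iff its parent is already a taxonomy node and the edge
#' does not create a directed cycle; a child already placed elsewhere gains
#' an additional parent (the taxonomy is a DAG, not a tree). All rejections
#' are counted by reason. Because placement requires the parent to exist, a
#' term missed in one pass can be placed in a later one — the reason K > 1
#' is useful.
#'
#' @param papers named list/vector of paper texts.
#' @param vocabulary a \linkS4class{Vocabulary}.
#' @param categories character vector of first-level category labels
#'   (normalized; attached under the root before the first pass).
#' @param backend a \linkS4class{GenerationBackend}.
#' @param K number of passes over the corpus (>= 0; 0 returns the seeded
#'   taxonomy).
#' @param m odd self-consistency sample count per relationship query.
#' @param seed stage seed.
#' @return list with elements \code{taxonomy} (the final
#'   \linkS4class{Taxonomy}) and \code{stats}, a data.frame of per-iteration
#'   counters: \code{k}, \code{nodes}, \code{edges}, \code{leaves},
#'   \code{accepted}, \code{rejected_cycles},
#'   \code{rejected_unknown_parent}, \code{rejected_not_in_vocabulary}.
#' @export
buildTaxonomy <- function(papers, vocabulary, categories, backend,
                          K = 3L, m = 3L, seed = 0L) {
  papers <- as.list(papers)
  if (!length(categories)) stop("categories must be non-empty")
  if (is.null(names(papers)) || any(!nzchar(names(papers))))
    names(papers) <- sprintf("paper%03d", seq_along(papers))
  K <- as.integer(K)
  if (K < 0L) .stopConfig("K must be >= 0")

  tx <- Taxonomy(data.frame(child = unique(categories),
                            parent = "thing", stringsAsFactors = FALSE))
  stats <- data.frame(k = integer(0), nodes = integer(0), edges = integer(0),
                      leaves = integer(0), accepted = integer(0),
                      rejected_cycles = integer(0),
                      rejected_unknown_parent = integer(0),
                      rejected_not_in_vocabulary = integer(0))

  for (k in seq_len(K)) {
    accepted <- 0L; rejCycle <- 0L; rejParent <- 0L; rejVocab <- 0L
    for (pid in names(papers)) {
      vocab_i <- paperVocabulary(vocabulary, pid)
      pairs <- queryRelationships(papers[[pid]], tx, vocab_i, backend,
                                  m = m, paperId = pid,
                                  seed = .deriveSeed(seed, "tax", k, pid))
      rejParent <- rejParent + attr(pairs, "nRejectedUnknownParent") %||% 0L
      rejVocab <- rejVocab + attr(pairs, "nRejectedNotInVocab") %||% 0L
      if (!nrow(pairs)) next
      pairs <- .canonicalPairOrder(pairs, tx)
      for (i in seq_len(nrow(pairs))) {
        s <- pairs$parent[i]; t <- pairs$child[i]
        if (!(s %in% tx@nodes)) { rejParent <- rejParent + 1L; next }
        if (wouldCreateCycle(tx, t, s)) { rejCycle <- rejCycle + 1L; next }
        before <- nrow(tx@edges)
        tx <- addEdge(tx, t, s)
        if (nrow(tx@edges) > before) accepted <- accepted + 1L
      }
    }
    stats <- rbind(stats, data.frame(
      k = k, nodes = length(tx@nodes), edges = nrow(tx@edges),
      leaves = length(taxonomyLeaves(tx)), accepted = accepted,
      rejected_cycles = rejCycle, rejected_unknown_parent = rejParent,
      rejected_not_in_vocabulary = rejVocab))
  }
  list(taxonomy = tx, stats = stats)
}

#' Report vocabulary terms never placed in the taxonomy
#'
#' Terms that failed placement in all passes are reported, never
#' force-attached to a fallback parent.
#'
#' @param taxonomy the built \linkS4class{Taxonomy}.
#' @param vocabulary the corpus \linkS4class{Vocabulary}.
#' @return character vector of unplaced lemma keys.
#' @export
unplacedTerms <- function(taxonomy, vocabulary) {
  sort(setdiff(vocabularyLemmas(vocabulary), taxonomy@nodes))
}
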