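## Planted-ontology worlds: a known ground-truth ontology + KG is generated,
## a synthetic corpus of "papers" is rendered from it (term mentions,
## acronym definitions, isA assertions, relation sentences), and the
## PlantedBackend answers prompts from the same ground truth under
## controllable omission/hallucination noise. This gives the pipeline a
## setting where the right answer is known exactly, so parameter recovery
## and noise robustness are measurable.

.SYLLABLES <- c("ba", "do", "fe", "gi", "ka", "lo", "mu", "ne", "pa", "ri",
                "ta", "ve", "cor", "lith", "fer", "bor", "sil", "cal",
                "nod", "plat")

.PREDICATES <- c("supported on", "interacts with", "derived from",
                 "bound to")

## deterministic pseudoword labels that are normalizeTerm fixpoints
.makeLabels <- function(n, nWords = 1L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < 50L * n) {
    tries <- tries + 1L
    word <- function() paste(sample(.SYLLABLES, sample(2:3, 1)),
                             collapse = "")
    lab <- paste(vapply(seq_len(nWords), function(i) word(), ""),
                 collapse = " ")
    if (identical(normalizeTerm(lab), lab) && !(lab %in% out))
      out <- c(out, lab)
  }
  if (length(out) < n) stop("could not generate enough unique labels")
  out
}

#' Specification of a planted ontology world
#'
#' @param depth number of class levels below the root (>= 2); level 1 holds
#'   the categories.
#' @param branching mean children per class; drives the level sizes.
#' @param multiparentRate probability a node at depth >= 2 gains a second
#'   parent from a shallower level (0 gives a tree).
#' @param nTerms total non-root nodes.
#' @param nPapers corpus size N.
#' @param factsPerPaper target isA assertions per rendered paper.
#' @param coverage fraction of assertable ground-truth edges stated
#'   somewhere in the corpus, in (0, 1].
#' @param assignment \code{"random"} (edges dealt round-robin) or
#'   \code{"staged"} (deepest edges in the earliest papers, the adversarial
#'   order for single-pass placement: a pass can only place a child whose
#'   parent is already in the taxonomy, so staged corpora need one pass per
#'   level).
#' @param nRelations planted relation triples between leaves.
#' @param acronymRate fraction of two-word terms given an acronym alias.
#' @param seed integer; the world is byte-identical for identical seeds.
#' @return a \code{PlantedSpec} list.
#' @export
plantedSpec <- function(depth = 4L, branching = 3, multiparentRate = 0,
                        nTerms = 60L, nPapers = 10L, factsPerPaper = 8L,
                        coverage = 1.0, assignment = c("random", "staged"),
                        nRelations = 6L, acronymRate = 0.25, seed = 1L) {
  assignment <- match.arg(assignment)
  if (depth < 2L) .stopConfig("depth must be >= 2")
  if (coverage <= 0 || coverage > 1)
    .stopConfig("coverage must be in (0, 1]")
  if (multiparentRate < 0 || multiparentRate > 1)
    .stopConfig("multiparentRate must be in [0, 1]")
  if (nPapers < 1L) .stopConfig("nPapers must be >= 1")
  list(depth = as.integer(depth), branching = branching,
       multiparentRate = multiparentRate, nTerms = as.integer(nTerms),
       nPapers = as.integer(nPapers),
       factsPerPaper = as.integer(factsPerPaper), coverage = coverage,
       assignment = assignment, nRelations = as.integer(nRelations),
       acronymRate = acronymRate, seed = as.integer(seed))
}

#' Generate a planted ontology, knowledge graph and rendered corpus
#'
#' Builds a rooted DAG of \code{nTerms} pseudoword terms in \code{depth}
#' levels (each node's primary parent one level up; optional extra parents
#' make it a DAG), instantiates the ground-truth KG from its leaves, plants
#' relation triples and acronym aliases, and renders a corpus of
#' \code{nPapers} synthetic papers whose sentences assert term mentions,
#' acronym definitions, isA facts and relations. Deterministic given the
#' spec seed.
#'
#' @param spec a \code{\link{plantedSpec}}.
#' @return a planted-world list with elements \code{taxonomy} (ground-truth
#'   \linkS4class{Taxonomy}), \code{schema}, \code{kg}, \code{categories},
#'   \code{levels} (named integer, node -> level), \code{papers} (named
#'   list: \code{text}, \code{mentionSurfaces}, \code{acronyms},
#'   \code{isaFacts}, \code{triples}, noise pools), \code{spec}.
#' @export
generatePlantedWorld <- function(spec = plantedSpec()) {
  .withSeed(spec$seed, {
    ## level sizes roughly geometric in `branching`, summing to nTerms
    raw <- spec$branching^(seq_len(spec$depth) - 1L)
    sizes <- pmax(1L, round(spec$nTerms * raw / sum(raw)))
    while (sum(sizes) > spec$nTerms) sizes[which.max(sizes)] <-
        sizes[which.max(sizes)] - 1L
    while (sum(sizes) < spec$nTerms) sizes[which.max(raw)] <-
        sizes[which.max(raw)] + 1L

    nOneWord <- sum(sizes[1]) + sum(sizes[-1]) %/% 2L
    labels <- c(.makeLabels(nOneWord, 1L),
                .makeLabels(spec$nTerms - nOneWord, 2L))
    labels <- sample(labels)
    levels <- rep(seq_len(spec$depth), times = sizes)
    byLevel <- split(labels, levels)
    names(byLevel) <- as.character(seq_len(spec$depth))

    edges <- data.frame(child = character(0), parent = character(0),
                        stringsAsFactors = FALSE)
    edges <- rbind(edges, data.frame(child = byLevel[["1"]],
                                     parent = "thing",
                                     stringsAsFactors = FALSE))
    for (l in 2:spec$depth) {
      for (node in byLevel[[as.character(l)]]) {
        p <- sample(byLevel[[as.character(l - 1L)]], 1L)
        edges <- rbind(edges, data.frame(child = node, parent = p,
                                         stringsAsFactors = FALSE))
        if (stats::runif(1) < spec$multiparentRate) {
          shallower <- setdiff(unlist(byLevel[as.character(seq_len(l - 1L))]),
                               p)
          if (length(shallower))
            edges <- rbind(edges,
                           data.frame(child = node,
                                      parent = sample(shallower, 1L),
                                      stringsAsFactors = FALSE))
        }
      }
    }
    gt <- Taxonomy(edges)
    categories <- sort(byLevel[["1"]])
    inst <- instantiateKG(gt)

    ## planted relation triples between leaves
    lv <- taxonomyLeaves(gt)
    nRel <- min(spec$nRelations,
                if (length(lv) >= 2) length(lv) * (length(lv) - 1L) else 0L)
    triples <- data.frame(subject = character(0), predicate = character(0),
                          object = character(0), stringsAsFactors = FALSE)
    if (nRel > 0) {
      seenKeys <- character(0)
      while (nrow(triples) < nRel) {
        so <- sample(lv, 2L)
        pr <- sample(.PREDICATES, 1L)
        key <- .tripleKey(so[1], pr, so[2])
        if (key %in% seenKeys) next
        seenKeys <- c(seenKeys, key)
        triples <- rbind(triples,
                         data.frame(subject = so[1], predicate = pr,
                                    object = so[2],
                                    stringsAsFactors = FALSE))
      }
    }
    kg <- inst$kg
    kg@relations <- triples[order(triples$subject, triples$predicate,
                                  triples$object), , drop = FALSE]
    rownames(kg@relations) <- NULL

    ## acronym aliases for a fraction of the two-word terms
    twoWord <- labels[grepl(" ", labels, fixed = TRUE)]
    nAcro <- round(spec$acronymRate * length(twoWord))
    acroTerms <- if (nAcro > 0) sample(twoWord, nAcro) else character(0)
    acronyms <- data.frame(acronym = character(0), expansion = character(0),
                           stringsAsFactors = FALSE)
    usedAcr <- character(0)
    for (tm in acroTerms) {
      parts <- strsplit(tm, " ", fixed = TRUE)[[1]]
      acr <- toupper(paste0(substr(parts, 1, 2), collapse = ""))
      ## acronym lemma must not collide with a planted term key
      if (acr %in% usedAcr || nchar(acr) >= nchar(tm) ||
          tolower(acr) %in% labels) next
      usedAcr <- c(usedAcr, acr)
      acronyms <- rbind(acronyms,
                        data.frame(acronym = acr, expansion = tm,
                                   stringsAsFactors = FALSE))
    }

    ## assertable isA facts = all ground-truth edges except root edges
    ## (categories are seeded under the root by the builder itself)
    assertable <- edges[edges$parent != "thing", , drop = FALSE]
    nCovered <- max(1L, ceiling(spec$coverage * nrow(assertable)))
    covered <- assertable[sample(nrow(assertable), nCovered), , drop = FALSE]
    childLevel <- stats::setNames(levels, labels)

    paperOfFact <- if (spec$assignment == "staged") {
      ## deepest facts into the earliest papers: contiguous blocks
      covered <- covered[order(-childLevel[covered$child]), , drop = FALSE]
      block <- ceiling(nrow(covered) / spec$nPapers)
      rep(seq_len(spec$nPapers), each = block)[seq_len(nrow(covered))]
    } else {
      covered <- covered[sample(nrow(covered)), , drop = FALSE]
      rep_len(seq_len(spec$nPapers), nrow(covered))
    }

    paperOfTriple <- if (nrow(triples))
      sample(spec$nPapers, nrow(triples), replace = TRUE) else integer(0)

    papers <- list()
    vocabAll <- c(labels)
    for (i in seq_len(spec$nPapers)) {
      pid <- sprintf("paper%03d", i)
      facts <- covered[paperOfFact == i, , drop = FALSE]
      ptrip <- triples[paperOfTriple == i, , drop = FALSE]
      mentioned <- unique(c(facts$child, facts$parent,
                            ptrip$subject, ptrip$object))
      ## pad with extra mentions so every paper has some vocabulary
      extra <- sample(labels, min(4L, length(labels)))
      mentioned <- unique(c(mentioned, extra))
      pAcro <- acronyms[acronyms$expansion %in% mentioned, , drop = FALSE]

      sent <- c(
        sprintf("The role of %s is discussed in this work.", mentioned),
        if (nrow(pAcro)) sprintf("%s (%s) is examined in detail.",
                                 pAcro$expansion, pAcro$acronym),
        if (nrow(facts)) sprintf("%s is a kind of %s.",
                                 facts$child, facts$parent),
        if (nrow(ptrip)) sprintf("%s %s %s.", ptrip$subject,
                                 ptrip$predicate, ptrip$object))
      text <- paste(sent, collapse = " ")

      ## deterministic per-paper noise pools for the planted backend
      fabTerms <- paste0("zx", .makeLabels(3L, 1L))
      fabAcr <- data.frame(acronym = c("ZXQ", "ZXW"),
                           expansion = paste0("zx", .makeLabels(2L, 2L)),
                           stringsAsFactors = FALSE)
      gtKeys <- .pairKey(edges$child, edges$parent)
      spur <- list()
      guard <- 0L
      while (length(spur) < 3L && guard < 200L) {
        guard <- guard + 1L
        cand <- sample(vocabAll, 2L)
        if (.pairKey(cand[2], cand[1]) %in% gtKeys) next
        spur[[length(spur) + 1L]] <- data.frame(
          parent = cand[1], child = cand[2], stringsAsFactors = FALSE)
      }
      spuriousPairs <- do.call(rbind, spur)
      spuriousTriples <- data.frame(
        subject = c(sample(vocabAll, 1L), "zxunknown"),
        predicate = c("confused with", "measured by"),
        object = c(sample(vocabAll, 1L), sample(vocabAll, 1L)),
        stringsAsFactors = FALSE)

      papers[[pid]] <- list(
        text = text,
        mentionSurfaces = sort(unique(c(mentioned, pAcro$acronym))),
        acronyms = pAcro,
        isaFacts = data.frame(parent = facts$parent, child = facts$child,
                              stringsAsFactors = FALSE),
        triples = ptrip,
        fabricatedTerms = fabTerms,
        fabricatedAcronyms = fabAcr,
        spuriousPairs = spuriousPairs,
        spuriousTriples = spuriousTriples)
    }

    list(taxonomy = gt, schema = inst$schema, kg = kg,
         categories = categories,
         levels = childLevel,
         papers = papers,
         fabricatedCategories = paste0("zxcat", c("one", "two")),
         vocabLemmas = sort(labels),
         spec = spec)
  })
}

#' Corpus texts of a planted world
#'
#' @param world a planted world from \code{\link{generatePlantedWorld}}.
#' @return named character vector of paper texts.
#' @export
plantedCorpus <- function(world) {
  vapply(world$papers, `[[`, "", "text")
}
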