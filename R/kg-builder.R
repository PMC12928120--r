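## Stages 4-5: knowledge-graph instantiation and relation extraction.
## Leaves of the taxonomy have no children, so they are the lowest-level
## concepts of the schema and become KG instances; non-leaf nodes are
## classes. Relation triples are extracted per paper and filtered to the
## vocabulary.

#' Instantiate the knowledge graph from a taxonomy
#'
#' Taxonomy leaves become KG instances; non-leaf, non-root nodes become
#' schema classes (the root is always a class); every leaf-parent isA edge
#' becomes an instance-of link, so a multi-parent leaf instantiates several
#' classes.
#'
#' @param taxonomy a \linkS4class{Taxonomy} with at least one non-root node.
#' @return list with elements \code{schema} (\linkS4class{OntologySchema})
#'   and \code{kg} (\linkS4class{KnowledgeGraph}, relations empty).
#' @export
instantiateKG <- function(taxonomy) {
  nonroot <- setdiff(taxonomy@nodes, taxonomy@root)
  if (!length(nonroot))
    stop("taxonomy must have at least one non-root node")
  inst <- taxonomyLeaves(taxonomy)
  cls <- setdiff(nonroot, inst)
  e <- taxonomy@edges
  io <- e[e$child %in% inst, , drop = FALSE]
  instanceOf <- data.frame(instance = io$child, class = io$parent,
                           stringsAsFactors = FALSE)
  instanceOf <- instanceOf[order(instanceOf$instance, instanceOf$class), ,
                           drop = FALSE]
  rownames(instanceOf) <- NULL
  schema <- new("OntologySchema", taxonomy = taxonomy,
                classes = sort(cls), instances = sort(inst))
  kg <- new("KnowledgeGraph", instances = sort(inst),
            instanceOf = instanceOf,
            relations = data.frame(subject = character(0),
                                   predicate = character(0),
                                   object = character(0),
                                   stringsAsFactors = FALSE))
  list(schema = schema, kg = kg)
}

#' KnowledgeGraph accessors
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @return \code{kgInstances}: instance keys; \code{kgRelations}: the triple
#'   data.frame; \code{kgInstanceOf}: the instance-of link table.
#' @export
kgInstances <- function(kg) sort(kg@instances)

#' @rdname kgInstances
#' @export
kgRelations <- function(kg) kg@relations

#' @rdname kgInstances
#' @export
kgInstanceOf <- function(kg) kg@instanceOf

.normalizePredicate <- function(p) {
  .collapseWS(tolower(as.character(p)))
}

#' Extract vocabulary-filtered relation triples from one paper
#'
#' Prompts the backend for subject--predicate--object triples under
#' self-consistency, normalizes endpoints with \code{\link{normalizeTerm}}
#' (acronym aliases resolve to their expansion's lemma key) and predicates
#' by case-folding/whitespace collapsing, then retains only triples whose
#' subject and object are vocabulary entries. Malformed rows are skipped
#' and counted.
#'
#' @param paperText text of the paper.
#' @param vocabulary a \linkS4class{Vocabulary}.
#' @param backend a \linkS4class{GenerationBackend}.
#' @param m odd self-consistency sample count.
#' @param paperId paper id.
#' @param seed request seed.
#' @return data.frame of deduplicated triples (\code{subject},
#'   \code{predicate}, \code{object}); attribute \code{nDropped} counts
#'   rejected proposals.
#' @export
extractRelations <- function(paperText, vocabulary, backend, m = 3L,
                             paperId = "paper", seed = 0L) {
  empty <- data.frame(subject = character(0), predicate = character(0),
                      object = character(0), stringsAsFactors = FALSE)
  lemmas <- vocabularyLemmas(vocabulary)
  if (!length(lemmas)) {
    attr(empty, "nDropped") <- 0L
    return(empty)
  }
  req <- generationRequest("triple_extract",
                           list(text = paperText, paperId = paperId,
                                vocab = lemmas),
                           seed = seed)
  trips <- tryCatch(selfConsistent(backend, req, m = m),
    ontokit_config_error = function(e) stop(e),
    error = function(e) {
      warning("triple extraction failed for paper '", paperId, "': ",
              conditionMessage(e))
      NULL
    })
  if (is.null(trips) || !is.data.frame(trips) || !nrow(trips)) {
    attr(empty, "nDropped") <- 0L
    return(empty)
  }
  names(trips)[1:3] <- c("subject", "predicate", "object")
  nIn <- nrow(trips)
  subj <- resolveAlias(vocabulary, normalizeTerm(trips$subject))
  obj <- resolveAlias(vocabulary, normalizeTerm(trips$object))
  pred <- .normalizePredicate(trips$predicate)
  ok <- nzchar(pred) & subj %in% lemmas & obj %in% lemmas
  out <- unique(data.frame(subject = subj[ok], predicate = pred[ok],
                           object = obj[ok], stringsAsFactors = FALSE))
  out <- out[order(out$subject, out$predicate, out$object), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nDropped") <- nIn - sum(ok)
  out
}

#' Extract relations across a corpus and attach them to a KG
#'
#' @param papers named list/vector of paper texts.
#' @param kg a \linkS4class{KnowledgeGraph} (from
#'   \code{\link{instantiateKG}}).
#' @inheritParams extractRelations
#' @return the \linkS4class{KnowledgeGraph} with deduplicated relations.
#' @export
extractCorpusRelations <- function(papers, kg, vocabulary, backend, m = 3L,
                                   seed = 0L) {
  papers <- as.list(papers)
  if (is.null(names(papers)) || any(!nzchar(names(papers))))
    names(papers) <- sprintf("paper%03d", seq_along(papers))
  all <- lapply(names(papers), function(pid)
    extractRelations(papers[[pid]], vocabulary, backend, m = m,
                     paperId = pid, seed = .deriveSeed(seed, "rel", pid)))
  rel <- unique(do.call(rbind, c(all, list(kg@relations))))
  rel <- rel[order(rel$subject, rel$predicate, rel$object), , drop = FALSE]
  rownames(rel) <- NULL
  kg@relations <- rel
  kg
}

#' Merge the knowledge graph with the ontology backbone
#'
#' Extends the KG's relation edges with the taxonomy's isA edges, producing
#' one labeled multigraph: relation triples keep their predicates with
#' \code{edge_type = "relation"}; each (child, parent) isA edge becomes an
#' edge labeled \code{isA} with \code{edge_type = "isA"}. When the two edge
#' sets are disjoint the merged edge count is their sum.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param taxonomy the \linkS4class{Taxonomy} the KG was derived from.
#' @return data.frame with columns \code{from}, \code{to}, \code{predicate},
#'   \code{edge_type}; exportable with \code{\link{writeGraphML}} and
#'   \code{\link{writeNTriples}}.
#' @export
mergeKgOntology <- function(kg, taxonomy) {
  r <- kg@relations
  relEdges <- data.frame(from = r$subject, to = r$object,
                         predicate = r$predicate,
                         edge_type = rep("relation", nrow(r)),
                         stringsAsFactors = FALSE)
  e <- taxonomyEdges(taxonomy)
  isaEdges <- data.frame(from = e$child, to = e$parent,
                         predicate = rep("isA", nrow(e)),
                         edge_type = rep("isA", nrow(e)),
                         stringsAsFactors = FALSE)
  out <- rbind(relEdges, isaEdges)
  rownames(out) <- NULL
  out
}

#' Write relation triples as TSV
#'
#' @param relations triple data.frame (\code{subject}, \code{predicate},
#'   \code{object}).
#' @param path file path.
#' @export
writeTriplesTSV <- function(relations, path) {
  utils::write.table(relations[, c("subject", "predicate", "object")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
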