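#' @import methods
NULL

.emptyEdges <- function() {
  data.frame(child = character(0), parent = character(0),
             stringsAsFactors = FALSE)
}

#' Taxonomy: a rooted directed acyclic graph of isA relationships
#'
#' The ontology backbone. Nodes are lemma-normalized term keys plus the
#' distinguished root (the universal concept \dQuote{Thing}, stored under its
#' lemma key \code{"thing"}). Edges are (child, parent) isA pairs; edges point
#' child-to-parent, while root-to-node paths follow the opposite
#' (parent-to-child) direction. Multiple parents are allowed, so the structure
#' is a DAG, not necessarily a tree.
#'
#' Validity requires: a non-empty root present among the nodes; no self-edges;
#' no duplicate edges; acyclicity; and every non-root node reachable from the
#' root.
#'
#' @slot root single character, the root term key.
#' @slot nodes character vector of all term keys including the root.
#' @slot edges data.frame with character columns \code{child} and
#'   \code{parent}.
#' @export
setClass("Taxonomy",
  representation(root = "character", nodes = "character", edges = "data.frame"),
  prototype(root = "thing", nodes = "thing", edges = .emptyEdges()))

setValidity("Taxonomy", function(object) {
  msgs <- character(0)
  if (length(object@root) != 1L || !nzchar(object@root))
    msgs <- c(msgs, "root must be a single non-empty string")
  if (!(object@root %in% object@nodes))
    msgs <- c(msgs, "root must be among the nodes")
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "duplicate node keys")
  e <- object@edges
  if (!all(c("child", "parent") %in% names(e)))
    msgs <- c(msgs, "edges must have columns child, parent")
  else if (nrow(e)) {
    if (any(e$child == e$parent)) msgs <- c(msgs, "self-edges are not allowed")
    if (anyDuplicated(.pairKey(e$child, e$parent)))
      msgs <- c(msgs, "duplicate edges")
    if (!all(c(e$child, e$parent) %in% object@nodes))
      msgs <- c(msgs, "edge endpoints must be nodes")
    if (object@root %in% e$child) msgs <- c(msgs, "root cannot have a parent")
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$parent, to = e$child), directed = TRUE,
      vertices = object@nodes)
    if (!igraph::is_dag(g)) msgs <- c(msgs, "taxonomy contains a cycle")
    else {
      reach <- igraph::subcomponent(g, object@root, mode = "out")$name
      missing <- setdiff(object@nodes, reach)
      if (length(missing))
        msgs <- c(msgs, paste("nodes unreachable from root:",
                              paste(missing, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Vocabulary: normalized domain terms with surface forms and acronym aliases
#'
#' One entry per lemma key. Each entry records every raw surface form observed
#' in the corpus, the papers that mention it, and any acronym aliases resolved
#' to it. The canonical surface form is the earliest-seen one in corpus order.
#'
#' @slot entries data.frame with columns \code{lemma} and \code{canonical}.
#' @slot surfaceForms named list, lemma key -> character vector of raw forms.
#' @slot aliases named list, lemma key -> character vector of acronym surface
#'   forms attached to that entry; acronym lemma keys also index
#'   \code{aliasTo}.
#' @slot aliasTo named character, acronym lemma key -> expansion lemma key.
#' @slot papers named list, lemma key -> character vector of paper ids.
#' @slot perPaper named list, paper id -> character vector of lemma keys
#'   (the per-paper vocabularies V_i).
#' @export
setClass("Vocabulary",
  representation(entries = "data.frame", surfaceForms = "list",
                 aliases = "list", aliasTo = "character",
                 papers = "list", perPaper = "list"))

setValidity("Vocabulary", function(object) {
  msgs <- character(0)
  if (!all(c("lemma", "canonical") %in% names(object@entries)))
    msgs <- c(msgs, "entries must have columns lemma, canonical")
  else {
    if (anyDuplicated(object@entries$lemma))
      msgs <- c(msgs, "lemma keys must be unique")
    if (any(!nzchar(object@entries$lemma)))
      msgs <- c(msgs, "empty lemma key")
  }
  if (length(object@aliasTo) &&
      !all(object@aliasTo %in% object@entries$lemma))
    msgs <- c(msgs, "alias targets must be vocabulary entries")
  if (length(msgs)) msgs else TRUE
})

#' KnowledgeGraph: instances, instance-of links, and relation triples
#'
#' Instances are taxonomy leaves; \code{instanceOf} links each instance to the
#' class(es) it instantiates (its taxonomy parents); \code{relations} holds
#' open-vocabulary subject--predicate--object triples between vocabulary
#' terms.
#'
#' @slot instances character vector of instance term keys.
#' @slot instanceOf data.frame with columns \code{instance}, \code{class}.
#' @slot relations data.frame with columns \code{subject}, \code{predicate},
#'   \code{object}.
#' @export
setClass("KnowledgeGraph",
  representation(instances = "character", instanceOf = "data.frame",
                 relations = "data.frame"),
  prototype(instances = character(0),
            instanceOf = data.frame(instance = character(0),
                                    class = character(0),
                                    stringsAsFactors = FALSE),
            relations = data.frame(subject = character(0),
                                   predicate = character(0),
                                   object = character(0),
                                   stringsAsFactors = FALSE)))

setValidity("KnowledgeGraph", function(object) {
  msgs <- character(0)
  if (!all(c("instance", "class") %in% names(object@instanceOf)))
    msgs <- c(msgs, "instanceOf must have columns instance, class")
  r <- object@relations
  if (!all(c("subject", "predicate", "object") %in% names(r)))
    msgs <- c(msgs, "relations must have columns subject, predicate, object")
  else if (nrow(r)) {
    if (any(!nzchar(r$predicate))) msgs <- c(msgs, "empty predicate")
    if (anyDuplicated(.tripleKey(r$subject, r$predicate, r$object)))
      msgs <- c(msgs, "duplicate triples")
  }
  if (nrow(object@instanceOf) &&
      !all(object@instanceOf$instance %in% object@instances))
    msgs <- c(msgs, "instanceOf rows must reference known instances")
  if (length(msgs)) msgs else TRUE
})

#' OntologySchema: a taxonomy partitioned into classes and instances
#'
#' Leaves of the taxonomy are instances; non-leaf, non-root nodes are classes
#' (the root is always a class and is kept out of both sets so that classes
#' and instances partition the non-root nodes).
#'
#' @slot taxonomy the backing \linkS4class{Taxonomy}.
#' @slot classes character vector of non-leaf, non-root term keys.
#' @slot instances character vector of leaf term keys.
#' @export
setClass("OntologySchema",
  representation(taxonomy = "Taxonomy", classes = "character",
                 instances = "character"))

setValidity("OntologySchema", function(object) {
  msgs <- character(0)
  nonroot <- setdiff(object@taxonomy@nodes, object@taxonomy@root)
  if (!setequal(union(object@classes, object@instances), nonroot))
    msgs <- c(msgs, "classes and instances must partition the non-root nodes")
  if (length(intersect(object@classes, object@instances)))
    msgs <- c(msgs, "classes and instances must be disjoint")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy: %d nodes, %d isA edges, %d leaves (root '%s')\n",
              length(object@nodes), nrow(object@edges),
              length(taxonomyLeaves(object)), object@root))
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d entries, %d acronym aliases, %d papers\n",
              nrow(object@entries), length(object@aliasTo),
              length(object@perPaper)))
})

setMethod("show", "KnowledgeGraph", function(object) {
  cat(sprintf(
    "KnowledgeGraph: %d instances, %d instance-of links, %d relation triples\n",
    length(object@instances), nrow(object@instanceOf),
    nrow(object@relations)))
})

setMethod("show", "OntologySchema", function(object) {
  cat(sprintf("OntologySchema: %d classes + root, %d instances\n",
              length(object@classes), length(object@instances)))
})
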