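#' Construct a Taxonomy
#'
#' Builds a validated rooted isA DAG from an edge table. The root node is
#' created implicitly; nodes are the union of the root and all edge
#' endpoints.
#'
#' @param edges data.frame with character columns \code{child} and
#'   \code{parent} (one isA assertion per row), or \code{NULL} for a
#'   root-only taxonomy.
#' @param root root term key; defaults to \code{"thing"}, the lemma of the
#'   universal concept \dQuote{Thing}.
#' @return a \linkS4class{Taxonomy}.
#' @examples
#' tx <- Taxonomy(data.frame(child = c("alkane", "alkyne"),
#'                           parent = c("functional group", "functional group")))
#' @export
Taxonomy <- function(edges = NULL, root = "thing") {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(new("Taxonomy", root = root, nodes = root, edges = .emptyEdges()))
  }
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(root, edges$child, edges$parent)))
  new("Taxonomy", root = root, nodes = nodes, edges = edges)
}

#' @describeIn Taxonomy root term key accessor.
#' @param x a Taxonomy.
#' @export
taxonomyRoot <- function(x) x@root

#' @describeIn Taxonomy all node keys (including the root), sorted.
#' @export
taxonomyNodes <- function(x) sort(x@nodes)

#' @describeIn Taxonomy the (child, parent) isA edge table, canonically
#'   ordered.
#' @export
taxonomyEdges <- function(x) {
  e <- x@edges[order(x@edges$child, x@edges$parent), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' @describeIn Taxonomy leaf nodes: nodes with no children. Never contains
#'   the root unless the taxonomy is root-only.
#' @export
taxonomyLeaves <- function(x) {
  sort(setdiff(x@nodes, x@edges$parent))
}

## children / parents lookup as named lists (internal)
.childrenMap <- function(x) split(x@edges$child, x@edges$parent)
.parentsMap <- function(x) split(x@edges$parent, x@edges$child)

#' Would inserting an isA edge create a directed cycle?
#'
#' The cycle guard of the incremental taxonomy builder: an edge
#' (child isA parent) is admissible only if the parent is not reachable from
#' the child when walking parent-to-child. A self-pair (child equal to
#' parent) is reported as a cycle, not an error. The taxonomy is never
#' modified; the parent need not exist yet and the child may be new.
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param child,parent term keys of the candidate isA pair.
#' @return \code{TRUE} iff inserting the edge would create a cycle.
#' @export
wouldCreateCycle <- function(taxonomy, child, parent) {
  stopifnot(length(child) == 1L, length(parent) == 1L)
  if (child == parent) return(TRUE)
  if (!(child %in% taxonomy@nodes)) return(FALSE)  # fresh leaf never cycles
  ## DFS downward from child along parent->child edges
  kids <- .childrenMap(taxonomy)
  stack <- child
  seen <- character(0)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (n %in% seen) next
    seen <- c(seen, n)
    ch <- kids[[n]]
    if (is.null(ch)) next
    if (parent %in% ch) return(TRUE)
    stack <- c(stack, setdiff(ch, seen))
  }
  parent %in% seen
}

#' Insert an isA edge under the cycle guard
#'
#' Adds (child isA parent) to the taxonomy. The parent must already exist
#' (top-down construction); a duplicate edge is an idempotent no-op; an edge
#' that would create a cycle, a self-edge, or a parent edge onto the root is
#' an error. Use \code{\link{wouldCreateCycle}} to test first.
#'
#' @inheritParams wouldCreateCycle
#' @return the grown \linkS4class{Taxonomy}.
#' @export
addEdge <- function(taxonomy, child, parent) {
  stopifnot(length(child) == 1L, length(parent) == 1L, nzchar(child))
  if (!(parent %in% taxonomy@nodes))
    stop("parent '", parent, "' is not in the taxonomy")
  if (child == taxonomy@root)
    stop("the root cannot be given a parent")
  key <- .pairKey(child, parent)
  if (key %in% .pairKey(taxonomy@edges$child, taxonomy@edges$parent))
    return(taxonomy)  # idempotent duplicate
  if (wouldCreateCycle(taxonomy, child, parent))
    stop("edge (", child, " isA ", parent, ") would create a cycle")
  e <- rbind(taxonomy@edges,
             data.frame(child = child, parent = parent,
                        stringsAsFactors = FALSE))
  e <- e[order(e$child, e$parent), , drop = FALSE]
  rownames(e) <- NULL
  taxonomy@edges <- e
  taxonomy@nodes <- sort(unique(c(taxonomy@nodes, child)))
  taxonomy
}

#' Enumerate all root-to-node paths
#'
#' Returns every distinct directed path from the root to \code{node},
#' following edges parent-to-child. In a tree there is exactly one path per
#' node; in a DAG a node reachable through several parents has several. The
#' result is ordered canonically (lexicographically by node sequence) so
#' enumeration is deterministic.
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param node an existing term key.
#' @return list of character vectors, each starting at the root and ending
#'   at \code{node}.
#' @export
enumerateRootPaths <- function(taxonomy, node) {
  if (!(node %in% taxonomy@nodes))
    stop("node '", node, "' not found in taxonomy")
  if (node == taxonomy@root) return(list(taxonomy@root))
  parents <- .parentsMap(taxonomy)
  ## walk upward child->parent, building paths root-first
  recurse <- function(n) {
    if (n == taxonomy@root) return(list(n))
    ps <- parents[[n]]
    out <- list()
    for (p in sort(ps)) {
      for (pp in recurse(p)) out[[length(out) + 1L]] <- c(pp, n)
    }
    out
  }
  paths <- recurse(node)
  keys <- vapply(paths, paste, "", collapse = "␟")
  paths[order(keys)]
}

## all root paths for every node: named list of lists (internal)
.allRootPaths <- function(taxonomy, includeRoot = FALSE) {
  nodes <- taxonomy@nodes
  if (!includeRoot) nodes <- setdiff(nodes, taxonomy@root)
  out <- lapply(nodes, function(n) enumerateRootPaths(taxonomy, n))
  names(out) <- nodes
  out
}

## ---- serialization -------------------------------------------------------

#' Read/write the canonical ontology JSON
#'
#' The canonical interchange format:
#' \code{{root, edges: [[child, parent], ...], instances: [...],
#' surface_forms: {lemma: [forms]}}}. Nodes and edges are serialized in
#' lexicographic order so equal taxonomies yield byte-identical files.
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param path file path.
#' @param instances optional character vector of instance keys (taxonomy
#'   leaves, typically).
#' @param surfaceForms optional named list of surface forms per lemma.
#' @return \code{readOntologyJSON} returns a list with elements
#'   \code{taxonomy}, \code{instances}, \code{surfaceForms}.
#' @export
writeOntologyJSON <- function(taxonomy, path, instances = NULL,
                              surfaceForms = NULL) {
  e <- taxonomyEdges(taxonomy)
  obj <- list(
    root = taxonomy@root,
    edges = unname(Map(c, e$child, e$parent)),
    instances = as.list(sort(instances %||% character(0))),
    surface_forms = surfaceForms %||% stats::setNames(list(), character(0)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeOntologyJSON
#' @export
readOntologyJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  edges <- if (length(obj$edges)) {
    data.frame(child = vapply(obj$edges, function(p) p[[1]], ""),
               parent = vapply(obj$edges, function(p) p[[2]], ""),
               stringsAsFactors = FALSE)
  } else NULL
  list(taxonomy = Taxonomy(edges, root = obj$root),
       instances = unlist(obj$instances) %||% character(0),
       surfaceForms = obj$surface_forms)
}

#' Read/write taxonomy edge lists as TSV
#'
#' Two-column (child, parent) tab-separated file with one header line.
#'
#' @inheritParams writeOntologyJSON
#' @export
writeEdgeTSV <- function(taxonomy, path) {
  utils::write.table(taxonomyEdges(taxonomy), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeTSV
#' @param root root key used when reconstructing the taxonomy.
#' @export
readEdgeTSV <- function(path, root = "thing") {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  Taxonomy(e, root = root)
}

#' Convert a taxonomy to an igraph object
#'
#' Directed graph with edges parent-to-child (the direction of root-to-node
#' paths).
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @return an \code{igraph} graph.
#' @export
taxonomyToIgraph <- function(taxonomy) {
  igraph::graph_from_data_frame(
    data.frame(from = taxonomy@edges$parent, to = taxonomy@edges$child),
    directed = TRUE, vertices = taxonomyNodes(taxonomy))
}

#' Export a taxonomy (or merged graph) to GraphML
#'
#' @param x a \linkS4class{Taxonomy} or a merged-graph edge table as produced
#'   by \code{\link{mergeKgOntology}}.
#' @param path file path.
#' @export
writeGraphML <- function(x, path) {
  g <- if (is(x, "Taxonomy")) {
    gg <- taxonomyToIgraph(x)
    igraph::E(gg)$edge_type <- "isA"
    igraph::E(gg)$predicate <- "isA"
    gg
  } else {
    igraph::graph_from_data_frame(x, directed = TRUE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

## escape for N-Triples literals/IRIs
.ntEscape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x
}

.ntIRI <- function(kind, label) {
  paste0("<urn:ontokit:", kind, ":",
         utils::URLencode(label, reserved = TRUE), ">")
}

#' Write isA and relation edges as N-Triples
#'
#' Line-oriented RDF serialization: each taxonomy edge becomes a triple with
#' the predicate label \code{isA} (a subclass-of-like predicate); each
#' knowledge-graph relation keeps its own predicate label. Terms and
#' predicates are minted as \code{urn:ontokit:} IRIs, percent-encoded.
#'
#' @param edges data.frame with columns \code{from}, \code{predicate},
#'   \code{to} (as from \code{\link{mergeKgOntology}}), or a
#'   \linkS4class{Taxonomy}.
#' @param path file path.
#' @export
writeNTriples <- function(edges, path) {
  if (is(edges, "Taxonomy")) {
    e <- taxonomyEdges(edges)
    edges <- data.frame(from = e$child, predicate = "isA", to = e$parent,
                        stringsAsFactors = FALSE)
  }
  lines <- sprintf("%s %s %s .",
                   .ntIRI("term", .ntEscape(edges$from)),
                   .ntIRI("rel", .ntEscape(edges$predicate)),
                   .ntIRI("term", .ntEscape(edges$to)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNTriples
#' @return \code{readNTriples} returns the edge data.frame
#'   (\code{from}, \code{predicate}, \code{to}).
#' @export
readNTriples <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  dec <- function(iri) {
    utils::URLdecode(sub("^<urn:ontokit:[a-z]+:(.*)>$", "\\1", iri))
  }
  parts <- strsplit(trimws(sub("\\s+\\.$", "", lines)), "\\s+")
  data.frame(from = vapply(parts, function(p) dec(p[[1]]), ""),
             predicate = vapply(parts, function(p) dec(p[[2]]), ""),
             to = vapply(parts, function(p) dec(p[[3]]), ""),
             stringsAsFactors = FALSE)
}
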