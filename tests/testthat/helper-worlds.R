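# Test fixtures built in code: small taxonomies from compact edge strings,
# and random rooted DAGs over a shared label pool (so a "ground truth" and a
# "reconstruction" drawn independently overlap partially).

# tx("a>thing", "b>a") builds a Taxonomy with edges child>parent
tx <- function(...) {
  specs <- c(...)
  if (!length(specs)) return(Taxonomy())
  parts <- strsplit(specs, ">", fixed = TRUE)
  Taxonomy(data.frame(child = vapply(parts, `[[`, "", 1L),
                      parent = vapply(parts, `[[`, "", 2L),
                      stringsAsFactors = FALSE))
}

edge_keys <- function(taxonomy) {
  e <- taxonomyEdges(taxonomy)
  paste(e$child, e$parent, sep = ">")
}

# random rooted DAG: each node's first parent is the root or an earlier
# node; extra parents appear with `multiparent` probability
random_taxonomy <- function(n_nodes, multiparent = 0.3,
                            labels = letters[1:12]) {
  nodes <- sample(labels, n_nodes)
  edges <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  placed <- "thing"
  for (nd in nodes) {
    p <- sample(placed, 1L)
    edges <- rbind(edges, data.frame(child = nd, parent = p,
                                     stringsAsFactors = FALSE))
    extra <- setdiff(placed, p)
    if (length(extra) && stats::runif(1) < multiparent) {
      edges <- rbind(edges, data.frame(child = nd,
                                       parent = sample(extra, 1L),
                                       stringsAsFactors = FALSE))
    }
    placed <- c(placed, nd)
  }
  Taxonomy(edges)
}
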