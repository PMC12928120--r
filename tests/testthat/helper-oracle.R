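# Brute-force reference implementation of the taxonomy metric suite,
# written directly over raw (child, parent) edge tables: forward DFS from
# the root enumerates every path, candidate matches are scored exhaustively,
# ancestors come from an iterated transitive closure. Deliberately
# independent of the package's Taxonomy class and igraph.

oracle_all_paths <- function(edges, root = "thing") {
  kids <- split(as.character(edges$child), as.character(edges$parent))
  res <- list()
  walk <- function(node, path) {
    res[[length(res) + 1L]] <<- path
    for (ch in kids[[node]]) walk(ch, c(path, ch))
  }
  walk(root, root)
  res
}

# non-root node set of a path (endpoint included)
.o_set <- function(path, root) setdiff(path, root)

# all ancestors (reflexive) by iterating parent lookups to a fixed point
oracle_ancestors <- function(edges, root = "thing") {
  nodes <- unique(c(root, edges$child, edges$parent))
  anc <- lapply(nodes, function(n) n)
  names(anc) <- nodes
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      ch <- edges$child[i]; pa <- edges$parent[i]
      new <- union(anc[[ch]], anc[[pa]])
      if (length(new) != length(anc[[ch]])) {
        anc[[ch]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  anc
}

oracle_lca_set <- function(a, b, anc) {
  ca <- intersect(anc[[a]], anc[[b]])
  keep <- logical(length(ca))
  for (i in seq_along(ca)) {
    others <- setdiff(ca, ca[i])
    # ca[i] is "lowest" iff no other common ancestor descends from it
    keep[i] <- !any(vapply(others, function(d) ca[i] %in% anc[[d]], TRUE))
  }
  ca[keep]
}

# exhaustive best-match: max shared nodes, then shortest, then lexicographic
oracle_best_match <- function(gt_path, rec_paths, root) {
  endpoint <- gt_path[length(gt_path)]
  cands <- Filter(function(p) p[length(p)] == endpoint, rec_paths)
  if (!length(cands)) return(NULL)
  gs <- .o_set(gt_path, root)
  shared <- vapply(cands, function(p) length(intersect(.o_set(p, root), gs)),
                   0L)
  lens <- lengths(cands)
  keys <- vapply(cands, paste, "", collapse = "|")
  cands[[order(-shared, lens, keys)[1L]]]
}

oracle_metrics <- function(gt_edges, rec_edges, root = "thing") {
  gt_paths <- Filter(function(p) length(p) > 1L,
                     oracle_all_paths(gt_edges, root))
  rec_paths <- oracle_all_paths(rec_edges, root)
  rec_nodes <- unique(c(root, rec_edges$child, rec_edges$parent))
  gt_nodes <- setdiff(unique(c(gt_edges$child, gt_edges$parent)), root)

  recall <- numeric(0); prec <- numeric(0); acc <- numeric(0)
  aec <- numeric(0)
  for (p in gt_paths) {
    gs <- .o_set(p, root)
    m <- oracle_best_match(p, rec_paths, root)
    if (is.null(m)) {
      recall <- c(recall, 0)
      acc <- c(acc, 0)
      aec <- c(aec, length(gs))
    } else {
      ms <- .o_set(m, root)
      sh <- intersect(gs, ms)
      recall <- c(recall, length(sh) / length(gs))
      prec <- c(prec, length(sh) / length(ms))
      acc <- c(acc, as.numeric(length(sh) >= 1))
      aec <- c(aec, length(setdiff(gs, ms)) + length(setdiff(ms, gs)))
    }
  }
  hR <- mean(recall)
  hP <- if (length(prec)) mean(prec) else 0
  hF1 <- if (hP + hR == 0) 0 else 2 * hP * hR / (hP + hR)
  hAcc <- mean(acc)

  anc_gt <- oracle_ancestors(gt_edges, root)
  anc_rec <- oracle_ancestors(rec_edges, root)
  lca_ok <- logical(0)
  ns <- sort(gt_nodes)
  if (length(ns) >= 2) {
    for (i in seq_len(length(ns) - 1L)) for (j in (i + 1L):length(ns)) {
      a <- ns[i]; b <- ns[j]
      ok <- a %in% rec_nodes && b %in% rec_nodes &&
        length(intersect(oracle_lca_set(a, b, anc_gt),
                         oracle_lca_set(a, b, anc_rec))) > 0
      lca_ok <- c(lca_ok, ok)
    }
  }

  gt_leaves <- setdiff(unique(c(gt_edges$child, gt_edges$parent)),
                       c(gt_edges$parent, root))
  rec_leaves <- setdiff(unique(c(rec_edges$child, rec_edges$parent)),
                        c(rec_edges$parent, root))
  frac <- function(g, r) if (!length(g)) 1 else length(intersect(g, r)) / length(g)

  list(hP = hP, hR = hR, hF1 = hF1, hAcc = hAcc,
       AEC = mean(aec),
       LCA = if (length(lca_ok)) mean(lca_ok) else 1,
       term_accuracy = frac(gt_nodes, setdiff(rec_nodes, root)),
       leaf_accuracy = frac(gt_leaves, rec_leaves),
       kg_accuracy = frac(gt_leaves, rec_leaves))
}
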