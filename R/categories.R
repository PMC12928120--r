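## Stage 2: first taxonomy level. Top categories rarely sit in a single
## paper, so they are generated across the corpus with a long-context
## prompt, repeated under shuffled paper orders (long-context models are
## order-sensitive), then refined by self-consistent majority voting.

.truncateForContext <- function(text, charBudget) {
  if (nchar(text) <= charBudget) return(text)
  substr(text, 1L, charBudget)
}

#' Generate category samples under shuffled paper orders
#'
#' Each of the \code{SG} samples presents the corpus to the backend in an
#' independently shuffled order (seeded, logged in the \code{shuffles}
#' attribute) and asks for the main categories across the papers. Papers
#' are truncated to a per-paper character budget before prompting, since a
#' long-context prompt concatenates the whole corpus.
#'
#' @param papers named list/vector of paper texts.
#' @param backend a \linkS4class{GenerationBackend}.
#' @param SG number of generation samples (>= 1).
#' @param seed stage seed; shuffle s uses a substream derived from
#'   (seed, s).
#' @param charBudget per-paper character budget for the long-context
#'   payload.
#' @return list of \code{SG} character vectors (category sequences);
#'   attribute \code{shuffles} holds the logged permutations.
#' @export
generateCategorySamples <- function(papers, backend, SG = 5L, seed = 0L,
                                    charBudget = 4000L) {
  papers <- as.list(papers)
  if (!length(papers)) stop("empty corpus")
  if (SG < 1L) .stopConfig("SG must be >= 1")
  if (is.null(names(papers)) || any(!nzchar(names(papers))))
    names(papers) <- sprintf("paper%03d", seq_along(papers))
  samples <- vector("list", SG)
  shuffles <- vector("list", SG)
  for (s in seq_len(SG)) {
    perm <- .withSeed(.deriveSeed(seed, "shuffle", s),
                      sample(seq_along(papers)))
    shuffles[[s]] <- names(papers)[perm]
    payload <- list(
      paperIds = names(papers)[perm],
      texts = vapply(papers[perm], .truncateForContext, "",
                     charBudget = charBudget))
    req <- generationRequest("category_generate", payload,
                             sampleIndex = s, seed = seed)
    samples[[s]] <- as.character(generate(backend, req))
  }
  attr(samples, "shuffles") <- shuffles
  samples
}

#' Refine category samples by self-consistent majority vote
#'
#' Passes the raw generation samples to the backend's refinement role
#' \code{SR} times and keeps the strict-majority vote across the refinement
#' answers. Candidates are ranked by their support (occurrence count across
#' the generation samples) so that manual curation can truncate the list.
#'
#' @param samples list of category sequences from
#'   \code{\link{generateCategorySamples}}.
#' @param backend a \linkS4class{GenerationBackend}.
#' @param SR odd number of refinement samples.
#' @param seed stage seed.
#' @return data.frame of \code{CategoryCandidate}s with columns
#'   \code{label} (normalized), \code{support} (count across generation
#'   samples), \code{kept} (survived the refinement majority), ordered by
#'   non-increasing support then label.
#' @export
refineCategories <- function(samples, backend, SR = 3L, seed = 0L) {
  if (!length(samples)) stop("no category samples to refine")
  if (SR %% 2L == 0L) .stopConfig("SR must be odd, got ", SR)
  normSamples <- lapply(samples, function(s) unique(normalizeTerm(s)))
  req <- generationRequest("category_refine",
                           list(samples = normSamples), seed = seed)
  keptLabels <- normalizeTerm(selfConsistent(backend, req, m = SR))
  allLabels <- unlist(normSamples, use.names = FALSE)
  support <- table(allLabels)
  labels <- names(support)
  out <- data.frame(label = labels,
                    support = as.integer(support),
                    kept = labels %in% keptLabels,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curate the final category set
#'
#' Deterministic selection of the categories that seed the taxonomy's first
#' level, either by an explicit label subset or by top-k support among the
#' refined (kept) candidates. The choice is what a run manifest records.
#'
#' @param candidates data.frame from \code{\link{refineCategories}}.
#' @param keep either a character vector of candidate labels, an integer k
#'   (top-k kept candidates by support), or \code{"all"}.
#' @return character vector of final category labels (normalized).
#' @export
curateCategories <- function(candidates, keep = "all") {
  kept <- candidates[candidates$kept, , drop = FALSE]
  if (is.numeric(keep)) {
    k <- as.integer(keep)
    if (k < 1L) .stopConfig("top-k curation needs k >= 1")
    return(utils::head(kept$label, k))
  }
  if (identical(keep, "all")) return(kept$label)
  keep <- normalizeTerm(keep)
  unknown <- setdiff(keep, candidates$label)
  if (length(unknown))
    stop("unknown category label(s): ", paste(unknown, collapse = ", "))
  candidates$label[candidates$label %in% keep]
}
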