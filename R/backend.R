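## Pluggable text-generation backends. Every pipeline stage talks to a
## backend through generationRequest()/generate(); offline backends (scripted
## replay, planted-world oracle) make the whole pipeline runnable and
## testable without a live model.

.PROMPT_ROLES <- c("sentence_split", "term_extract", "acronym_extract",
                   "category_generate", "category_refine",
                   "relationship_query", "triple_extract")

#' Build a generation request
#'
#' A request carries the prompt role (which pipeline stage is asking), a
#' structured payload whose shape the role determines, and the pair
#' (seed, sampleIndex) that fully determines the response of any offline
#' backend.
#'
#' @param role one of \code{sentence_split}, \code{term_extract},
#'   \code{acronym_extract}, \code{category_generate},
#'   \code{category_refine}, \code{relationship_query},
#'   \code{triple_extract}.
#' @param payload named list; typical fields are \code{text},
#'   \code{paperId}, \code{taxonomyTerms}, \code{vocab}, \code{samples}.
#' @param sampleIndex 1-based index of the self-consistency sample.
#' @param seed integer seed for the request stream.
#' @return a \code{GenerationRequest} (list).
#' @export
generationRequest <- function(role, payload = list(), sampleIndex = 1L,
                              seed = 0L) {
  role <- match.arg(role, .PROMPT_ROLES)
  structure(list(role = role, payload = payload,
                 sampleIndex = as.integer(sampleIndex),
                 seed = as.integer(seed)),
            class = "GenerationRequest")
}

#' @rdname generationRequest
#' @param request a \code{GenerationRequest}.
#' @return \code{requestDigest} returns a short stable string identifying
#'   the request, used as the lookup key of the scripted backend.
#' @export
requestDigest <- function(request) {
  pl <- jsonlite::toJSON(request$payload, auto_unbox = TRUE, digits = NA)
  sprintf("%s:%d:%d", request$role, request$sampleIndex, .hashString(pl))
}

.payloadChars <- function(payload) {
  sum(nchar(unlist(lapply(payload, as.character)), type = "chars"), 0L)
}

#' GenerationBackend: the contract for text-generation engines
#'
#' Virtual parent of all backends. Every call through
#' \code{\link{generate}} is appended to the backend's ledger (role, a
#' payload-length token proxy, sample index), which makes the per-stage call
#' complexity of the pipeline directly measurable.
#'
#' @slot ledger environment holding the call log.
#' @export
setClass("GenerationBackend",
         representation("VIRTUAL", ledger = "environment"))

.newLedger <- function() {
  e <- new.env(parent = emptyenv())
  e$calls <- list()
  e
}

#' PlantedBackend: an oracle over a planted ground-truth world
#'
#' Answers every prompt role from a known ground-truth ontology, knowledge
#' graph and rendered corpus (see \code{\link{generatePlantedWorld}}),
#' corrupted by two noise processes applied independently per sample: each
#' true fact is dropped with probability \code{omissionRate}, and each
#' member of a deterministic per-paper pool of spurious facts (random
#' vocabulary pairs absent from the ground truth, or fabricated strings) is
#' injected with probability \code{hallucinationRate}. Identical
#' (seed, sampleIndex) pairs reproduce identical responses.
#'
#' @slot world planted-world list as returned by
#'   \code{\link{generatePlantedWorld}}.
#' @slot omissionRate,hallucinationRate per-sample noise probabilities in
#'   [0, 1].
#' @slot seed integer; the backend's own stream seed.
#' @export
setClass("PlantedBackend",
         contains = "GenerationBackend",
         representation(world = "list", omissionRate = "numeric",
                        hallucinationRate = "numeric", seed = "integer"))

setValidity("PlantedBackend", function(object) {
  ok <- function(r) length(r) == 1L && r >= 0 && r <= 1
  if (!ok(object@omissionRate)) return("omissionRate must be in [0, 1]")
  if (!ok(object@hallucinationRate))
    return("hallucinationRate must be in [0, 1]")
  TRUE
})

#' @rdname PlantedBackend-class
#' @param world,omissionRate,hallucinationRate,seed see slots.
#' @export
plantedBackend <- function(world, omissionRate = 0, hallucinationRate = 0,
                           seed = 1L) {
  new("PlantedBackend", world = world,
      omissionRate = as.numeric(omissionRate),
      hallucinationRate = as.numeric(hallucinationRate),
      seed = as.integer(seed), ledger = .newLedger())
}

#' ScriptedBackend: deterministic replay of recorded responses
#'
#' Maps a request digest (\code{\link{requestDigest}}) to a canned response;
#' unknown requests yield the configured default (empty). Fixture files are
#' YAML mappings digest -> response.
#'
#' @slot responses named list, digest -> response.
#' @export
setClass("ScriptedBackend",
         contains = "GenerationBackend",
         representation(responses = "list"))

#' @rdname ScriptedBackend-class
#' @param responses named list keyed by request digest.
#' @export
scriptedBackend <- function(responses = list()) {
  new("ScriptedBackend", responses = responses, ledger = .newLedger())
}

#' @rdname ScriptedBackend-class
#' @param path YAML fixture file.
#' @export
readScriptedBackend <- function(path) {
  scriptedBackend(yaml::read_yaml(path))
}

#' FunctionBackend: wrap an arbitrary response function
#'
#' Mostly used in tests, e.g. to model an adversarial generator that emits
#' fabricated terms.
#'
#' @slot fn function(request) -> response.
#' @export
setClass("FunctionBackend",
         contains = "GenerationBackend",
         representation(fn = "function"))

#' @rdname FunctionBackend-class
#' @param fn function of one argument (the request).
#' @export
functionBackend <- function(fn) {
  new("FunctionBackend", fn = fn, ledger = .newLedger())
}

#' Generate a structured response for a request
#'
#' Dispatches on the backend class; appends one row to the backend's call
#' ledger before responding. Offline backends are fully deterministic given
#' (backend state, seed, sampleIndex).
#'
#' @param backend a \linkS4class{GenerationBackend}.
#' @param request a \code{\link{generationRequest}}.
#' @return a role-dependent structured response: character vector of terms
#'   or categories, a (parent, child) pair data.frame, a triple data.frame,
#'   or a character vector of sentences.
#' @export
setGeneric("generate", function(backend, request) standardGeneric("generate"))

.logCall <- function(backend, request) {
  led <- backend@ledger
  led$calls[[length(led$calls) + 1L]] <- list(
    role = request$role,
    payload_chars = .payloadChars(request$payload),
    sample_index = request$sampleIndex)
  invisible(NULL)
}

setMethod("generate", "ScriptedBackend", function(backend, request) {
  .logCall(backend, request)
  backend@responses[[requestDigest(request)]] %||% character(0)
})

setMethod("generate", "FunctionBackend", function(backend, request) {
  .logCall(backend, request)
  backend@fn(request)
})

setMethod("generate", "PlantedBackend", function(backend, request) {
  .logCall(backend, request)
  .plantedRespond(backend, request)
})

#' Inspect and reset a backend's call ledger
#'
#' @param backend a \linkS4class{GenerationBackend}.
#' @return \code{ledgerTable}: data.frame (role, payload_chars,
#'   sample_index), one row per call; \code{ledgerCounts}: named integer
#'   vector of calls per role.
#' @export
ledgerTable <- function(backend) {
  calls <- backend@ledger$calls
  if (!length(calls)) {
    return(data.frame(role = character(0), payload_chars = integer(0),
                      sample_index = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(role = vapply(calls, `[[`, "", "role"),
             payload_chars = vapply(calls, `[[`, 0L, "payload_chars"),
             sample_index = vapply(calls, `[[`, 0L, "sample_index"),
             stringsAsFactors = FALSE)
}

#' @rdname ledgerTable
#' @export
ledgerCounts <- function(backend) {
  tab <- ledgerTable(backend)
  counts <- stats::setNames(integer(length(.PROMPT_ROLES)), .PROMPT_ROLES)
  if (nrow(tab)) {
    tt <- table(tab$role)
    counts[names(tt)] <- as.integer(tt)
  }
  counts
}

#' @rdname ledgerTable
#' @export
resetLedger <- function(backend) {
  backend@ledger$calls <- list()
  invisible(backend)
}

## ---- self-consistency ----------------------------------------------------

.responseKeys <- function(resp) {
  if (is.data.frame(resp)) {
    if (!nrow(resp)) return(character(0))
    do.call(paste, c(unname(resp), list(sep = "␟")))
  } else as.character(resp)
}

.keysToResponse <- function(keys, template) {
  if (is.data.frame(template)) {
    if (!length(keys)) return(template[0, , drop = FALSE])
    parts <- strsplit(keys, "␟", fixed = TRUE)
    out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(out) <- names(template)
    rownames(out) <- NULL
    out
  } else keys
}

#' Self-consistency: majority vote over repeated samples
#'
#' Issues the same request \code{m} times (sample indices 1..m) and keeps
#' exactly the items that occur in more than \code{threshold * m} of the
#' samples (strict majority by default). Sampling the generator repeatedly
#' and majority-voting suppresses hallucinations: an item a noisy generator
#' emits with per-sample probability below 1/2 survives with probability
#' that vanishes as \code{m} grows, while a true item retained with
#' per-sample probability p > 1/2 survives with the binomial tail
#' probability P(Bin(m, p) > m/2).
#'
#' @param backend a \linkS4class{GenerationBackend}.
#' @param request a \code{\link{generationRequest}}; its sampleIndex is
#'   overridden by the loop.
#' @param m odd number of samples (>= 1); an even \code{m} is a
#'   configuration error.
#' @param threshold vote threshold as a fraction of \code{m}; items kept
#'   when count > threshold * m.
#' @return the aggregated response, same shape as a single sample, ranked by
#'   support (descending count, then item order); attributes \code{support}
#'   (named counts over all observed items) and \code{nSamples}.
#' @export
selfConsistent <- function(backend, request, m, threshold = 0.5) {
  m <- as.integer(m)
  if (m < 1L) .stopConfig("self-consistency sample count m must be >= 1")
  if (m %% 2L == 0L)
    .stopConfig("self-consistency sample count m must be odd, got ", m)
  samples <- vector("list", m)
  for (i in seq_len(m)) {
    req <- request
    req$sampleIndex <- i
    samples[[i]] <- generate(backend, req)
  }
  template <- samples[[1L]]
  keysets <- lapply(samples, function(s) unique(.responseKeys(s)))
  allKeys <- unlist(keysets, use.names = FALSE)
  if (!length(allKeys)) {
    out <- .keysToResponse(character(0), template)
    attr(out, "support") <- integer(0)
    attr(out, "nSamples") <- m
    return(out)
  }
  counts <- table(factor(allKeys, levels = unique(allKeys)))
  keep <- counts[counts > threshold * m]
  keep <- keep[order(-as.integer(keep), names(keep))]
  out <- .keysToResponse(names(keep), template)
  attr(out, "support") <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "nSamples") <- m
  out
}

## ---- planted-world response construction ---------------------------------

.sampleSeed <- function(backend, request, extra = "") {
  .deriveSeed(backend@seed, request$role, extra,
              request$payload$paperId %||% "",
              request$seed, request$sampleIndex)
}

## drop each element independently with probability `rate`
.omit <- function(keys, rate) {
  if (!length(keys) || rate <= 0) return(keys)
  keys[stats::runif(length(keys)) >= rate]
}

## include each pool element independently with probability `rate`
.inject <- function(pool, rate) {
  if (!length(pool) || rate <= 0) return(pool[0])
  pool[stats::runif(length(pool)) < rate]
}

.plantedPaper <- function(backend, request) {
  pid <- request$payload$paperId
  if (is.null(pid) || !pid %in% names(backend@world$papers))
    stop("planted backend: unknown paperId '", pid %||% "<missing>", "'")
  backend@world$papers[[pid]]
}

.plantedRespond <- function(backend, request) {
  role <- request$role
  om <- backend@omissionRate
  hal <- backend@hallucinationRate
  seed <- .sampleSeed(backend, request)
  switch(role,
    sentence_split = splitSentences(request$payload$text, backend = NULL),
    term_extract = {
      paper <- .plantedPaper(backend, request)
      sentence <- request$payload$text %||% paper$text
      normSent <- .verifyNormalize(sentence)
      present <- paper$mentionSurfaces[
        vapply(paper$mentionSurfaces,
               function(s) grepl(.verifyNormalize(s), normSent,
                                 fixed = TRUE), TRUE)]
      .withSeed(seed, {
        kept <- .omit(present, om)
        junk <- .inject(paper$fabricatedTerms, hal)
        sample(unique(c(kept, junk)))
      })
    },
    acronym_extract = {
      paper <- .plantedPaper(backend, request)
      tru <- paper$acronyms
      .withSeed(seed, {
        keys <- .responseKeys(tru)
        kept <- tru[keys %in% .omit(keys, om), , drop = FALSE]
        junk <- .inject(seq_len(nrow(paper$fabricatedAcronyms)), hal)
        rbind(kept, paper$fabricatedAcronyms[junk, , drop = FALSE])
      })
    },
    category_generate = {
      cats <- backend@world$categories
      .withSeed(seed, {
        kept <- .omit(cats, om)
        junk <- .inject(backend@world$fabricatedCategories, hal)
        sample(c(kept, junk))
      })
    },
    category_refine = {
      ## honest refiner: rank provided sample items by frequency, keep the
      ## majority across generation samples, then apply this sample's noise
      samples <- request$payload$samples
      allItems <- unlist(samples, use.names = FALSE)
      counts <- sort(table(allItems), decreasing = TRUE)
      keep <- names(counts)[counts > length(samples) / 2]
      .withSeed(seed, {
        kept <- .omit(keep, om)
        junk <- .inject(backend@world$fabricatedCategories, hal)
        c(kept, junk)
      })
    },
    relationship_query = {
      paper <- .plantedPaper(backend, request)
      taxTerms <- request$payload$taxonomyTerms %||% character(0)
      vocab <- request$payload$vocab %||% character(0)
      facts <- paper$isaFacts
      facts <- facts[facts$parent %in% taxTerms & facts$child %in% vocab, ,
                     drop = FALSE]
      .withSeed(seed, {
        keys <- .responseKeys(facts)
        kept <- facts[keys %in% .omit(keys, om), , drop = FALSE]
        junk <- .inject(seq_len(nrow(paper$spuriousPairs)), hal)
        out <- rbind(kept, paper$spuriousPairs[junk, , drop = FALSE])
        rownames(out) <- NULL
        out
      })
    },
    triple_extract = {
      paper <- .plantedPaper(backend, request)
      tru <- paper$triples
      .withSeed(seed, {
        keys <- .responseKeys(tru)
        kept <- tru[keys %in% .omit(keys, om), , drop = FALSE]
        junk <- .inject(seq_len(nrow(paper$spuriousTriples)), hal)
        out <- rbind(kept, paper$spuriousTriples[junk, , drop = FALSE])
        rownames(out) <- NULL
        out
      })
    },
    stop("unhandled prompt role: ", role))
}
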