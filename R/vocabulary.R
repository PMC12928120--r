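## Stage 1: vocabulary extraction — terms, acronyms, lemmatization.
## Every surface form that survives this stage is verified against the
## source text, so an arbitrarily unreliable generator cannot inject
## vocabulary that was never written.

## abbreviations whose trailing dot must not end a sentence
.ABBREV <- c("e.g", "i.e", "etc", "cf", "vs", "ca", "al", "fig", "figs",
             "eq", "eqs", "ref", "refs", "dr", "prof", "mr", "mrs", "ms",
             "no", "vol", "approx", "resp", "et")

#' Split text into sentences
#'
#' Deterministic, abbreviation-aware rule-based splitter: sentence
#' boundaries are terminal punctuation (., ?, !) followed by whitespace and
#' an upper-case letter, digit or opening bracket, except after common
#' abbreviations (e.g., i.e., etc., Fig., et al.) , single-initial
#' capitals, and inside decimal numbers. The concatenation of the returned
#' sentences reproduces the input modulo whitespace; a text with no internal
#' boundary comes back as a single sentence. A generation backend may be
#' supplied to delegate splitting to the \code{sentence_split} prompt role
#' instead.
#'
#' @param text a single character string.
#' @param backend optional \linkS4class{GenerationBackend}; \code{NULL}
#'   (default) uses the rule-based splitter.
#' @param seed seed forwarded to the backend request.
#' @return character vector of non-empty sentences, in order.
#' @export
splitSentences <- function(text, backend = NULL, seed = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.null(backend)) {
    req <- generationRequest("sentence_split", list(text = text), seed = seed)
    out <- generate(backend, req)
    out <- out[nzchar(trimws(out))]
    if (length(out)) return(trimws(out))
  }
  txt <- .collapseWS(text)
  if (!nzchar(txt)) return(character(0))
  ## protect dots that do not end sentences (case-preserving)
  protected <- txt
  for (ab in .ABBREV) {
    pat <- paste0("(?i)(?<![A-Za-z])(",
                  gsub(".", "\\\\.", ab, fixed = TRUE), ")\\.")
    protected <- gsub(pat, "\\1․", protected, perl = TRUE)
  }
  ## decimal numbers
  protected <- gsub("(?<=[0-9])\\.(?=[0-9])", "․", protected,
                    perl = TRUE)
  pieces <- strsplit(protected, "(?<=[.?!])\\s+(?=[A-Z0-9(\"'“])",
                     perl = TRUE)[[1L]]
  pieces <- gsub("․", ".", pieces, fixed = TRUE)
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

## small irregular-plural map used by the lemmatizer
.IRREGULAR <- c(children = "child", feet = "foot", geese = "goose",
                men = "man", mice = "mouse", teeth = "tooth",
                women = "woman", analyses = "analysis", bases = "basis",
                hypotheses = "hypothesis", theses = "thesis",
                matrices = "matrix", indices = "index",
                vertices = "vertex", appendices = "appendix",
                phenomena = "phenomenon", criteria = "criterion",
                leaves = "leaf", halves = "half", lives = "life",
                knives = "knife", oxides = "oxide", species = "species",
                series = "series", gases = "gas")

.lemmaToken <- function(tok) {
  hit <- .IRREGULAR[tok]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(tok)
  if (n > 4L && endsWith(tok, "ies")) return(paste0(substr(tok, 1, n - 3), "y"))
  if (n > 4L && (endsWith(tok, "xes") || endsWith(tok, "zes") ||
                 endsWith(tok, "ches") || endsWith(tok, "shes") ||
                 endsWith(tok, "sses")))
    return(substr(tok, 1, n - 2))
  if (n > 3L && endsWith(tok, "s") &&
      !endsWith(tok, "ss") && !endsWith(tok, "us") && !endsWith(tok, "is") &&
      !endsWith(tok, "'s"))
    return(substr(tok, 1, n - 1))
  tok
}

#' Normalize a surface form to its lemma key
#'
#' Deterministic and idempotent concept normalization: case-fold, strip
#' punctuation (hyphens become spaces, so \dQuote{Single-Atom Catalysts} and
#' \dQuote{Single Atom Catalyst} coincide), collapse whitespace, and
#' lemmatize each token with rule-based English plural reduction plus a
#' small irregular map. Surface forms sharing a lemma key are treated as the
#' same concept throughout the pipeline.
#'
#' @param surface character vector of raw surface forms.
#' @return character vector of lemma keys.
#' @examples
#' normalizeTerm("Single-Atom Catalysts")  # "single atom catalyst"
#' @export
normalizeTerm <- function(surface) {
  vapply(surface, function(x) {
    x <- tolower(enc2utf8(as.character(x)))
    x <- gsub("[^a-z0-9]+", " ", x)
    x <- .collapseWS(x)
    if (!nzchar(x)) return("")
    toks <- strsplit(x, " ", fixed = TRUE)[[1L]]
    paste(vapply(toks, .lemmaToken, ""), collapse = " ")
  }, "", USE.NAMES = FALSE)
}

## normalization used for verification matching (no lemmatization: the test
## is "was this written in the text", up to case/hyphen/whitespace variants)
.verifyNormalize <- function(x) {
  x <- tolower(enc2utf8(as.character(x)))
  x <- gsub("-", " ", x, fixed = TRUE)
  .collapseWS(x)
}

#' Verify that a proposed surface form occurs in a text
#'
#' The anti-hallucination filter of vocabulary extraction: a backend
#' proposal survives only if it occurs in the source text. Matching is
#' performed on normalized text by default (case-folded, hyphens to spaces,
#' whitespace collapsed), since hyphenation and casing variants of a term
#' are the same concept; \code{mode = "raw"} requires an exact substring.
#'
#' @param surface character vector of proposed forms.
#' @param text the source text.
#' @param mode \code{"normalized"} (default) or \code{"raw"}.
#' @return logical vector.
#' @export
verifySurface <- function(surface, text, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  if (mode == "raw") {
    return(vapply(surface, function(s) grepl(s, text, fixed = TRUE), TRUE,
                  USE.NAMES = FALSE))
  }
  nt <- .verifyNormalize(text)
  vapply(surface, function(s) {
    ns <- .verifyNormalize(s)
    nzchar(ns) && grepl(ns, nt, fixed = TRUE)
  }, TRUE, USE.NAMES = FALSE)
}

#' Extract verified terms from one sentence
#'
#' Prompts the backend for the terms present in a sentence and discards
#' every proposal that does not pass \code{\link{verifySurface}} against the
#' sentence. Backend parse failures yield an empty set with a warning,
#' never an error.
#'
#' @param sentence one sentence of a source paper.
#' @param backend a \linkS4class{GenerationBackend}.
#' @param paperId paper identifier forwarded in the payload.
#' @param seed request seed.
#' @param verifyMode matching mode, see \code{\link{verifySurface}}.
#' @return character vector of verified surface forms; attribute
#'   \code{nRejected} counts discarded proposals.
#' @export
extractTerms <- function(sentence, backend, paperId = "paper",
                         seed = 0L, verifyMode = "normalized") {
  req <- generationRequest("term_extract",
                           list(text = sentence, paperId = paperId),
                           seed = seed)
  proposals <- tryCatch(generate(backend, req), error = function(e) {
    warning("term extraction failed for paper '", paperId, "': ",
            conditionMessage(e))
    character(0)
  })
  proposals <- unique(as.character(proposals))
  proposals <- proposals[nzchar(trimws(proposals))]
  ok <- verifySurface(proposals, sentence, mode = verifyMode)
  out <- proposals[ok]
  attr(out, "nRejected") <- sum(!ok)
  out
}

#' Extract verified acronym pairs from a paper
#'
#' Prompts the backend to list acronyms with their expansions and keeps only
#' pairs whose acronym and expansion both occur in the paper and whose
#' acronym is strictly shorter than its expansion.
#'
#' @param paperText full text of the paper.
#' @inheritParams extractTerms
#' @return data.frame with columns \code{acronym}, \code{expansion}.
#' @export
extractAcronyms <- function(paperText, backend, paperId = "paper",
                            seed = 0L, verifyMode = "normalized") {
  req <- generationRequest("acronym_extract",
                           list(text = paperText, paperId = paperId),
                           seed = seed)
  pairs <- tryCatch(generate(backend, req), error = function(e) {
    warning("acronym extraction failed for paper '", paperId, "': ",
            conditionMessage(e))
    NULL
  })
  empty <- data.frame(acronym = character(0), expansion = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(pairs) || !is.data.frame(pairs) || !nrow(pairs)) return(empty)
  names(pairs)[1:2] <- c("acronym", "expansion")
  ok <- nchar(pairs$acronym) < nchar(pairs$expansion) &
    verifySurface(pairs$acronym, paperText, mode = verifyMode) &
    verifySurface(pairs$expansion, paperText, mode = verifyMode)
  out <- unique(pairs[ok, c("acronym", "expansion"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Build the corpus vocabulary
#'
#' Runs term and acronym extraction over every paper, normalizes all
#' verified surface forms with \code{\link{normalizeTerm}}, and merges forms
#' sharing a lemma key into single entries (canonical surface form =
#' earliest seen in corpus order). Acronyms become aliases of their
#' expansion's entry rather than independent concepts, and the per-paper
#' vocabularies V_i are retained for the taxonomy stage.
#'
#' @param papers named character vector or named list of paper texts; names
#'   are paper ids.
#' @param backend a \linkS4class{GenerationBackend}.
#' @param seed stage seed (fanned out per paper/sentence).
#' @param splitIntoSentences set \code{FALSE} to prompt with whole papers
#'   (the sentence-splitting ablation).
#' @param verifyMode matching mode, see \code{\link{verifySurface}}.
#' @return a \linkS4class{Vocabulary}.
#' @export
buildVocabulary <- function(papers, backend, seed = 0L,
                            splitIntoSentences = TRUE,
                            verifyMode = "normalized") {
  papers <- as.list(papers)
  if (!length(papers)) stop("empty corpus: at least one paper is required")
  if (is.null(names(papers)) || any(!nzchar(names(papers))))
    names(papers) <- sprintf("paper%03d", seq_along(papers))

  seen <- list()      # lemma -> list(canonical, surfaces, papers)
  order_seen <- character(0)
  perPaper <- list()
  acroAll <- list()

  for (pid in names(papers)) {
    text <- papers[[pid]]
    units <- if (splitIntoSentences) splitSentences(text) else text
    lemmas_i <- character(0)
    for (u in units) {
      forms <- extractTerms(u, backend, paperId = pid,
                            seed = .deriveSeed(seed, "vocab", pid),
                            verifyMode = verifyMode)
      for (f in forms) {
        lem <- normalizeTerm(f)
        if (!nzchar(lem)) next
        if (is.null(seen[[lem]])) {
          seen[[lem]] <- list(canonical = f, surfaces = f, papers = pid)
          order_seen <- c(order_seen, lem)
        } else {
          seen[[lem]]$surfaces <- union(seen[[lem]]$surfaces, f)
          seen[[lem]]$papers <- union(seen[[lem]]$papers, pid)
        }
        lemmas_i <- union(lemmas_i, lem)
      }
    }
    acr <- extractAcronyms(text, backend, paperId = pid,
                           seed = .deriveSeed(seed, "acro", pid),
                           verifyMode = verifyMode)
    if (nrow(acr)) acroAll[[pid]] <- acr
    perPaper[[pid]] <- sort(lemmas_i)
  }

  ## attach acronyms as aliases of their expansion's entry
  aliasTo <- character(0)
  aliases <- list()
  for (pid in names(acroAll)) {
    acr <- acroAll[[pid]]
    for (i in seq_len(nrow(acr))) {
      expLem <- normalizeTerm(acr$expansion[i])
      acrLem <- normalizeTerm(acr$acronym[i])
      if (!nzchar(expLem) || !nzchar(acrLem) || acrLem == expLem) next
      if (is.null(seen[[expLem]])) {
        ## expansion verified in text but not proposed as a term: add it
        seen[[expLem]] <- list(canonical = acr$expansion[i],
                               surfaces = acr$expansion[i], papers = pid)
        order_seen <- c(order_seen, expLem)
        perPaper[[pid]] <- sort(union(perPaper[[pid]], expLem))
      }
      aliases[[expLem]] <- union(aliases[[expLem]] %||% character(0),
                                 acr$acronym[i])
      aliasTo[acrLem] <- expLem
    }
  }

  ## acronyms are aliases, never independent entries: fold any entry whose
  ## lemma is an acronym key into its expansion's entry
  for (acrLem in names(aliasTo)) {
    if (!is.null(seen[[acrLem]])) {
      expLem <- aliasTo[[acrLem]]
      seen[[expLem]]$surfaces <- union(seen[[expLem]]$surfaces,
                                       seen[[acrLem]]$surfaces)
      seen[[expLem]]$papers <- union(seen[[expLem]]$papers,
                                     seen[[acrLem]]$papers)
      seen[[acrLem]] <- NULL
      order_seen <- setdiff(order_seen, acrLem)
      perPaper <- lapply(perPaper, function(v)
        sort(unique(ifelse(v == acrLem, expLem, v))))
    }
  }

  entries <- data.frame(
    lemma = order_seen,
    canonical = vapply(order_seen, function(l) seen[[l]]$canonical, ""),
    stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new("Vocabulary",
      entries = entries,
      surfaceForms = stats::setNames(
        lapply(order_seen, function(l) seen[[l]]$surfaces), order_seen),
      aliases = aliases,
      aliasTo = aliasTo,
      papers = stats::setNames(
        lapply(order_seen, function(l) sort(seen[[l]]$papers)), order_seen),
      perPaper = perPaper)
}

#' Vocabulary accessors
#'
#' @param vocabulary a \linkS4class{Vocabulary}.
#' @return \code{vocabularyLemmas}: all lemma keys; \code{paperVocabulary}:
#'   the lemma keys V_i of one paper; \code{resolveAlias}: maps lemma keys
#'   through the acronym alias table (acronym lemma -> expansion lemma,
#'   other keys unchanged).
#' @export
vocabularyLemmas <- function(vocabulary) sort(vocabulary@entries$lemma)

#' @rdname vocabularyLemmas
#' @param paperId paper id.
#' @export
paperVocabulary <- function(vocabulary, paperId) {
  vocabulary@perPaper[[paperId]] %||% character(0)
}

#' @rdname vocabularyLemmas
#' @param lemma character vector of lemma keys.
#' @export
resolveAlias <- function(vocabulary, lemma) {
  hit <- unname(vocabulary@aliasTo[lemma])
  ifelse(is.na(hit), lemma, hit)
}

#' Export a vocabulary as TSV or JSON
#'
#' TSV columns: lemma_key, canonical_surface, surface_forms (semicolon
#' joined), paper_ids (semicolon joined). JSON mirrors the slots.
#'
#' @param vocabulary a \linkS4class{Vocabulary}.
#' @param path file path.
#' @export
writeVocabularyTSV <- function(vocabulary, path) {
  e <- vocabulary@entries
  tab <- data.frame(
    lemma_key = e$lemma,
    canonical_surface = e$canonical,
    surface_forms = vapply(e$lemma, function(l)
      paste(vocabulary@surfaceForms[[l]], collapse = ";"), ""),
    paper_ids = vapply(e$lemma, function(l)
      paste(vocabulary@papers[[l]], collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVocabularyTSV
#' @export
writeVocabularyJSON <- function(vocabulary, path) {
  obj <- list(entries = vocabulary@entries,
              surface_forms = vocabulary@surfaceForms,
              aliases = vocabulary@aliases,
              alias_to = as.list(vocabulary@aliasTo),
              papers = vocabulary@papers,
              per_paper = vocabulary@perPaper)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
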