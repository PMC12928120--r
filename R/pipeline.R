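## End-to-end driver binding the five stages, with artifact serialization
## and a run manifest. A single user seed fans out into independent,
## reproducible per-stage substreams.

#' Validate a pipeline configuration
#'
#' @param config named list; recognized keys (with defaults):
#'   \code{K} (3) passes over the corpus, \code{m} (3, odd)
#'   self-consistency samples, \code{SG} (5) category generation samples,
#'   \code{SR} (3, odd) refinement samples, \code{seed} (1),
#'   \code{categoriesKeep} ("all"), \code{charBudget} (4000),
#'   \code{splitIntoSentences} (TRUE), \code{verifyMode} ("normalized").
#' @return the completed config list; signals an
#'   \code{ontokit_config_error} on invalid settings.
#' @export
validateConfig <- function(config = list()) {
  defaults <- list(K = 3L, m = 3L, SG = 5L, SR = 3L, seed = 1L,
                   categoriesKeep = "all", charBudget = 4000L,
                   splitIntoSentences = TRUE, verifyMode = "normalized")
  config <- utils::modifyList(defaults, config)
  for (key in c("K", "m", "SG", "SR", "seed", "charBudget"))
    config[[key]] <- as.integer(config[[key]])
  if (config$K < 1L) .stopConfig("K must be >= 1")
  if (config$m < 1L || config$m %% 2L == 0L)
    .stopConfig("m must be odd and >= 1")
  if (config$SG < 1L) .stopConfig("SG must be >= 1")
  if (config$SR < 1L || config$SR %% 2L == 0L)
    .stopConfig("SR must be odd and >= 1")
  config
}

#' Run the five-stage pipeline end to end
#'
#' Vocabulary extraction, category generation + refinement (+ curation),
#' iterative taxonomy construction, KG instantiation and relation
#' extraction, in order. When \code{outDir} is given, every stage artifact
#' is serialized there: vocabulary TSV/JSON, category candidates TSV,
#' per-iteration taxonomy snapshots (canonical JSON) and stats TSV, the
#' ontology JSON, KG triples TSV/N-Triples, the merged KG+ontology GraphML,
#' the backend-call ledger and a manifest recording config, seeds and
#' package version.
#'
#' @param papers named list/vector of paper texts (or a directory path
#'   containing .txt/.md files, one paper per file).
#' @param backend a \linkS4class{GenerationBackend}.
#' @param config see \code{\link{validateConfig}}.
#' @param outDir optional output directory.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list: \code{vocabulary}, \code{candidates},
#'   \code{categories}, \code{taxonomy}, \code{stats}, \code{schema},
#'   \code{kg}, \code{merged}, \code{ledger}, \code{config}.
#' @export
runPipeline <- function(papers, backend, config = list(), outDir = NULL,
                        quiet = TRUE) {
  config <- validateConfig(config)
  if (is.character(papers) && length(papers) == 1L && dir.exists(papers)) {
    files <- sort(list.files(papers, pattern = "\\.(txt|md)$",
                             full.names = TRUE))
    if (!length(files)) stop("no .txt/.md papers found in ", papers)
    papers <- stats::setNames(
      lapply(files, function(f) paste(readLines(f, warn = FALSE),
                                      collapse = "\n")),
      sub("\\.(txt|md)$", "", basename(files)))
  }
  papers <- as.list(papers)
  if (!length(papers)) stop("empty corpus")
  if (is.null(names(papers)) || any(!nzchar(names(papers))))
    names(papers) <- sprintf("paper%03d", seq_along(papers))
  say <- function(...) if (!quiet) message(...)

  say("stage 1/5: vocabulary extraction over ", length(papers), " papers")
  vocab <- buildVocabulary(papers, backend,
                           seed = .deriveSeed(config$seed, "stage-vocab"),
                           splitIntoSentences = config$splitIntoSentences,
                           verifyMode = config$verifyMode)

  say("stage 2/5: category extraction (SG = ", config$SG,
      ", SR = ", config$SR, ")")
  samples <- generateCategorySamples(
    papers, backend, SG = config$SG,
    seed = .deriveSeed(config$seed, "stage-categories"),
    charBudget = config$charBudget)
  candidates <- refineCategories(
    samples, backend, SR = config$SR,
    seed = .deriveSeed(config$seed, "stage-categories"))
  categories <- curateCategories(candidates, keep = config$categoriesKeep)
  if (!length(categories))
    stop("category extraction produced no categories")

  say("stage 3/5: taxonomy construction (K = ", config$K,
      ", m = ", config$m, ")")
  built <- buildTaxonomy(papers, vocab, categories, backend,
                         K = config$K, m = config$m,
                         seed = .deriveSeed(config$seed, "stage-taxonomy"))

  say("stage 4/5: knowledge-graph instantiation")
  inst <- instantiateKG(built$taxonomy)

  say("stage 5/5: relation extraction")
  kg <- extractCorpusRelations(papers, inst$kg, vocab, backend,
                               m = config$m,
                               seed = .deriveSeed(config$seed,
                                                  "stage-relations"))
  merged <- mergeKgOntology(kg, built$taxonomy)

  result <- list(vocabulary = vocab, candidates = candidates,
                 categories = categories, taxonomy = built$taxonomy,
                 stats = built$stats, schema = inst$schema, kg = kg,
                 merged = merged, ledger = ledgerTable(backend),
                 config = config)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeVocabularyTSV(vocab, file.path(outDir, "vocabulary.tsv"))
    writeVocabularyJSON(vocab, file.path(outDir, "vocabulary.json"))
    utils::write.table(candidates,
                       file.path(outDir, "category_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeOntologyJSON(built$taxonomy, file.path(outDir, "ontology.json"),
                      instances = kgInstances(kg),
                      surfaceForms = vocab@surfaceForms)
    writeEdgeTSV(built$taxonomy, file.path(outDir, "taxonomy_edges.tsv"))
    utils::write.table(built$stats,
                       file.path(outDir, "iteration_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeTriplesTSV(kgRelations(kg), file.path(outDir, "kg_triples.tsv"))
    writeNTriples(merged, file.path(outDir, "kg_ontology.nt"))
    writeGraphML(merged, file.path(outDir, "kg_ontology.graphml"))
    jsonlite::write_json(
      list(config = config,
           package_version = as.character(utils::packageVersion("ontokit")),
           n_papers = length(papers),
           config_hash = .hashString(jsonlite::toJSON(config,
                                                      auto_unbox = TRUE)),
           ledger_counts = as.list(ledgerCounts(backend))),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    utils::write.table(result$ledger, file.path(outDir, "call_ledger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}

#' Closed-form backend-call counts per stage
#'
#' The pipeline's call complexity is linear in the corpus: the vocabulary
#' stage issues one term-extraction call per sentence (or per paper when
#' splitting is disabled) plus one acronym call per paper; the category
#' stage issues SG + SR calls; the taxonomy stage K * N * m; the relation
#' stage N * m. \code{expectedCalls} returns these closed forms for a given
#' configuration so measured ledgers can be checked against them.
#'
#' @param N number of papers.
#' @param nSentences total sentences over the corpus (for the per-sentence
#'   granularity; use \code{N} when splitting is disabled).
#' @param K,m,SG,SR pipeline parameters.
#' @return named integer vector with elements \code{vocabulary_terms},
#'   \code{vocabulary_acronyms}, \code{categories}, \code{taxonomy},
#'   \code{relations}.
#' @export
expectedCalls <- function(N, nSentences, K, m, SG, SR) {
  c(vocabulary_terms = as.integer(nSentences),
    vocabulary_acronyms = as.integer(N),
    categories = as.integer(SG + SR),
    taxonomy = as.integer(K * N * m),
    relations = as.integer(N * m))
}
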