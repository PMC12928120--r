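## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 31-bit polynomial string hash, used to fan a single user
## seed out into independent per-stage / per-request substreams. Exact in
## doubles: intermediate values stay below 2^53.
.hashString <- function(x) {
  x <- paste(as.character(x), collapse = "␟")
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 17
  for (b in bytes) h <- (h * 1159241 + b) %% 2147483647
  as.integer(h)
}

.deriveSeed <- function(seed, ...) {
  .hashString(paste(seed, ..., sep = "␟"))
}

## Evaluate expr under a temporary RNG state; restores the caller's stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopConfig <- function(...) {
  stop(structure(class = c("ontokit_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

## single-character unit separator keeps composite keys unambiguous
.pairKey <- function(child, parent) paste(child, parent, sep = "␟")

.tripleKey <- function(s, p, o) paste(s, p, o, sep = "␟")

.collapseWS <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}
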