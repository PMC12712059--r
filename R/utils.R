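#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals
#' (clustering restarts, subsampling) never perturb the caller's
#' random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a purpose-tagged sub-stream seed (kept below 2^31). Components
# that share one user seed (cohort generation, survival times, phenotype
# transitions) must not replay the same uniform sequence: R's
# sample(prob=) maps each uniform through sorted cumulative weights, so
# stream reuse induces perfect draw-by-draw correlation between stages.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 65536
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483399) + 1L
}

# Population (1/n) standard deviation; clustering and z-scoring use this
# so that a 3-value row (1,2,3) scales to (-1.2247, 0, 1.2247).
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# TSV writer with a schema-version comment line; readers in this package
# skip leading '#' lines.
write_schema_tsv <- function(df, path, schema = "tmephenotyper-tsv-1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", schema), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_schema_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
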