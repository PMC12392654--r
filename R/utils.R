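# Internal helpers: seeded sub-streams, versioned TSV IO, small checks.

#' @importFrom methods new validObject is slot
#' @importFrom stats rpois rbinom rnbinom rgamma rexp rnorm runif rlnorm
#'   ppois dpois pchisq p.adjust fisher.test qbeta rbeta ks.test setNames
#' @importFrom utils write.table read.delim head tail
NULL

# Derive a deterministic sub-seed for a named generator stage, so that adding
# stages never perturbs the draws of earlier ones.  Kept below 2^31.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * (7L + 13L * seq_along(utf8ToInt(stage))))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483563)
}

# Evaluate `expr` under the stage-specific seed, restoring the caller's RNG.
.withStageSeed <- function(seed, stage, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.stageSeed(seed, stage))
  expr
}

.assertCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x <= 0 || x != as.integer(x))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
}

# Versioned tab-separated tables: first line is a '#' comment carrying the
# table name and a major schema version; readers reject unknown majors.
.TABLE_VERSION <- 1L

#' Write a versioned tab-separated table
#'
#' All pipeline tables share this format: a leading `#` comment line naming
#' the table and its major schema version, then a header row and
#' tab-separated values.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param table table name recorded in the version line.
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path, table = "table") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# DNMburden %s v%d", table, .TABLE_VERSION), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a versioned tab-separated table
#'
#' Rejects files whose schema major version is newer than this package
#' understands.
#'
#' @param path file written by [writeTsv()].
#' @return a data.frame.
#' @export
readTsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# DNMburden")) {
    ver <- as.integer(sub(".* v(\\d+)$", "\\1", first))
    if (!is.na(ver) && ver > .TABLE_VERSION)
      stop("unsupported table schema version: ", ver, call. = FALSE)
  }
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Clamp p-values into [1e-300, 1] before log transforms.
.clampP <- function(p) pmin(pmax(p, 1e-300), 1)
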