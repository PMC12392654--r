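# Per-site functional score track: a CADD-like deleteriousness score for
# every reference position (one score per position, the max over alternate
# alleles), plus FATHMM-like and SpliceAI-like columns in [0, 1].

#' Generate per-site functional scores
#'
#' Every position receives a CADD-like score; each site independently falls
#' in the >= 15 tail with probability `caddTailFraction` (default 1.8%,
#' matching the "top ~1.8% of variants" interpretation of CADD 15), with an
#' exponential tail above 15 and a decreasing-density body below it.
#' FATHMM-like and SpliceAI-like scores are drawn in [0, 1], concentrated
#' near 0 as for real tracks. Deterministic under the config seed.
#'
#' @param reference DNAStringSet.
#' @param geneModels a [GeneModelSet-class] (unused by the draw itself; kept
#'   so score generation can later condition on annotation).
#' @param config a [SimConfig-class].
#' @return list with one element per chromosome, each a list of numeric
#'   vectors `cadd`, `fathmm`, `spliceai` of chromosome length.
#' @export
generateSiteScores <- function(reference, geneModels, config) {
  stopifnot(is(config, "SimConfig"))
  tail <- config@caddTailFraction
  .withStageSeed(config@seed, "scores", {
    out <- lapply(Biostrings::width(reference), function(L) {
      u <- runif(L)
      cadd <- numeric(L)
      hi <- u > 1 - tail
      cadd[hi] <- 15 + rexp(sum(hi), rate = 1 / 3)
      cadd[!hi] <- 15 * (u[!hi] / (1 - tail))^1.5
      list(cadd = cadd,
           fathmm = runif(L)^3,
           spliceai = rbeta(L, 0.1, 3))
    })
    names(out) <- names(reference)
    out
  })
}

# Look up per-position scores for (chrom, pos) vectors; NA outside bounds.
.scoreAt <- function(scores, chrom, pos, what = "cadd") {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    v <- scores[[ch]][[what]]
    p <- pos[sel]
    ok <- p >= 1 & p <= length(v)
    out[sel][ok] <- v[p[ok]]
  }
  out
}

#' Write a per-site score table for selected positions
#'
#' Emits a tab-separated table (chrom, pos, cadd, fathmm, spliceai). With
#' `positions = NULL` the whole genome is written; restricting to a GRanges
#' keeps files small for large genomes.
#'
#' @param scores from [generateSiteScores()].
#' @param path output file.
#' @param positions optional GRanges restricting the rows.
#' @export
writeScoreTable <- function(scores, path, positions = NULL) {
  rows <- lapply(names(scores), function(ch) {
    L <- length(scores[[ch]]$cadd)
    if (is.null(positions)) p <- seq_len(L)
    else {
      sel <- positions[as.character(GenomeInfoDb::seqnames(positions)) == ch]
      p <- unlist(lapply(seq_along(sel), function(i)
        seq(BiocGenerics::start(sel)[i], min(BiocGenerics::end(sel)[i], L))))
      p <- unique(sort(p))
    }
    if (!length(p)) return(NULL)
    data.frame(chrom = ch, pos = p,
               cadd = round(scores[[ch]]$cadd[p], 3),
               fathmm = round(scores[[ch]]$fathmm[p], 4),
               spliceai = round(scores[[ch]]$spliceai[p], 4))
  })
  writeTsv(do.call(rbind, rows), path, "site_scores")
}
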