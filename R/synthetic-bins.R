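# 1 kb background bins with heterogeneous expected rare-variant counts and
# Gnocchi-like constraint scores.

#' Compute beta for 1 kb bins
#'
#' beta is a bin's expected rare-variant count divided by the mean expected
#' count over all bins, so that mean(beta) over the full bin set is exactly 1.
#'
#' @param expectedRare numeric vector of per-bin expected rare-variant counts.
#' @return numeric vector of beta values.
#' @export
computeBeta <- function(expectedRare) {
  m <- mean(expectedRare)
  if (!is.finite(m) || m <= 0) stop("mean expected count must be > 0", call. = FALSE)
  expectedRare / m
}

#' Generate tiling 1 kb background bins
#'
#' Tiles each chromosome with non-overlapping 1000 bp windows (trailing
#' partial windows dropped), draws per-bin expected rare-variant counts from
#' a gamma law (`gammaShape`, `gammaScale`; default mean 1 with realistic
#' heterogeneity), derives beta via [computeBeta()], assigns a Gnocchi-like
#' constraint score, and flags each bin `coding_overlap` (intersects any
#' CDS), `genic_noncoding` (intersects a gene footprint but no CDS) or
#' `intergenic`.
#'
#' @param reference DNAStringSet.
#' @param geneModels a [GeneModelSet-class].
#' @param config a [SimConfig-class].
#' @return GRanges of width-1000 bins with mcols expected_rare, beta,
#'   gnocchi, region_flag.
#' @export
generateGnocchiBins <- function(reference, geneModels, config) {
  widths <- Biostrings::width(reference)
  if (any(widths < 1000L)) stop("chromosome shorter than 1 kb", call. = FALSE)
  si <- .refSeqinfo(reference)
  bins <- do.call(c, lapply(seq_along(widths), function(i) {
    nb <- widths[i] %/% 1000L
    GenomicRanges::GRanges(names(reference)[i],
      IRanges::IRanges(start = (seq_len(nb) - 1L) * 1000L + 1L, width = 1000L),
      seqinfo = si)
  }))
  .withStageSeed(config@seed, "bins", {
    exp_rare <- rgamma(length(bins), shape = config@gammaShape,
                       scale = config@gammaScale)
    gnocchi <- rnorm(length(bins), 0, 1.5)
    cds <- unlist(geneModels@cds, use.names = FALSE)
    fp <- footprints(geneModels)
    hasCds <- IRanges::overlapsAny(bins, cds, ignore.strand = TRUE)
    hasFp <- IRanges::overlapsAny(bins, fp, ignore.strand = TRUE)
    S4Vectors::mcols(bins) <- S4Vectors::DataFrame(
      expected_rare = exp_rare,
      beta = computeBeta(exp_rare),
      gnocchi = gnocchi,
      region_flag = ifelse(hasCds, "coding_overlap",
                           ifelse(hasFp, "genic_noncoding", "intergenic")))
    bins
  })
}

#' Write the bin table
#'
#' Tab-separated with BED-style 0-based half-open starts.
#' @param bins GRanges from [generateGnocchiBins()].
#' @param path output file.
#' @export
writeBinTable <- function(bins, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(bins)),
                   start = BiocGenerics::start(bins) - 1L,
                   end = BiocGenerics::end(bins),
                   expected_rare = S4Vectors::mcols(bins)$expected_rare,
                   beta = S4Vectors::mcols(bins)$beta,
                   gnocchi = S4Vectors::mcols(bins)$gnocchi,
                   region_flag = S4Vectors::mcols(bins)$region_flag)
  writeTsv(df, path, "gnocchi_bins")
}
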