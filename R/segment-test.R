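# Segment-based case-only test: noncoding DNMs aggregated over a gene's
# 1 kb bins, with bin-specific expected counts avg_count_1kb * beta.

#' Cohort background rate per 1 kb bin
#'
#' average_count_1kb = (number of qualifying noncoding DNMs falling inside
#' the bin universe) / (number of bins in the universe).
#'
#' @param dnms data.frame of noncoding DNM calls (chrom, pos).
#' @param bins GRanges bin universe (already restricted to the analyzed
#'   region class).
#' @return list with average_count_1kb, n_bins, n_dnms.
#' @export
computeBackground <- function(dnms, bins) {
  if (!length(bins)) stop("empty bin set", call. = FALSE)
  pts <- GenomicRanges::GRanges(dnms$chrom,
                                IRanges::IRanges(dnms$pos, width = 1L))
  n <- sum(IRanges::overlapsAny(pts, bins, ignore.strand = TRUE))
  list(average_count_1kb = n / length(bins), n_bins = length(bins), n_dnms = n)
}

#' Expected DNM count in one bin
#'
#' ExpectedDNM = average_count_1kb * beta.
#'
#' @param background from [computeBackground()].
#' @param beta per-bin beta value(s).
#' @return expected count (vectorized over beta).
#' @export
expectedBinCount <- function(background, beta) {
  background$average_count_1kb * beta
}

#' Map 1 kb bins to genes
#'
#' Genic mode: a bin maps to every gene whose noncoding footprint it
#' overlaps by >= 1 bp; bins intersecting any CDS (`coding_overlap`) are
#' excluded. With `singleAssignment = TRUE` each bin keeps only the gene
#' with the longest footprint overlap (ties by smaller gene id).
#' Intergenic mode: each intergenic bin maps to the gene nearest its
#' midpoint.
#'
#' @param bins GRanges from [generateGnocchiBins()].
#' @param geneModels a [GeneModelSet-class].
#' @param mode "genic" or "intergenic".
#' @param singleAssignment keep one gene per bin (genic mode).
#' @return data.frame (bin_index, gene_id) mapping rows of `bins` to genes.
#' @export
assignBinsToGenes <- function(bins, geneModels,
                              mode = c("genic", "intergenic"),
                              singleAssignment = FALSE) {
  mode <- match.arg(mode)
  flag <- S4Vectors::mcols(bins)$region_flag
  if (mode == "genic") {
    use <- which(flag == "genic_noncoding")
    fp <- footprints(geneModels)
    hits <- GenomicRanges::findOverlaps(bins[use], fp, ignore.strand = TRUE)
    q <- use[S4Vectors::queryHits(hits)]
    gid <- geneModels@genes$gene_id[S4Vectors::subjectHits(hits)]
    if (singleAssignment && length(q)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(bins)[q],
        IRanges::ranges(fp)[S4Vectors::subjectHits(hits)]))
      ord <- order(q, -ov, gid)
      q <- q[ord]; gid <- gid[ord]
      first <- !duplicated(q)
      q <- q[first]; gid <- gid[first]
    }
    data.frame(bin_index = q, gene_id = gid, stringsAsFactors = FALSE)
  } else {
    use <- which(flag == "intergenic")
    if (!length(use)) return(data.frame(bin_index = integer(0),
                                        gene_id = character(0)))
    mid <- (BiocGenerics::start(bins)[use] + BiocGenerics::end(bins)[use]) %/% 2L
    pts <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(bins)[use],
                                  IRanges::IRanges(mid, width = 1L))
    fp <- footprints(geneModels)
    hits <- GenomicRanges::distanceToNearest(pts, fp, select = "all",
                                             ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    gid <- geneModels@genes$gene_id[S4Vectors::subjectHits(hits)]
    d <- S4Vectors::mcols(hits)$distance
    ord <- order(q, d, gid)
    q <- q[ord]; gid <- gid[ord]
    first <- !duplicated(q)
    data.frame(bin_index = use[q[first]], gene_id = gid[first],
               stringsAsFactors = FALSE)
  }
}

#' Run the segment-based case-only enrichment test
#'
#' Per gene: observed = case noncoding DNMs falling inside the gene's bins;
#' expected = sum over its bins of average_count_1kb * beta; p-value from
#' the case-only Poisson tail. The background is computed from the same
#' cohort over the same bin universe (all genic-noncoding bins for genic
#' mode, intergenic bins for intergenic mode). By default beta is rescaled
#' to unit mean over the analyzed universe so that, with single-assignment
#' mapping, the per-gene expected counts conserve the cohort total.
#' An optional CADD restriction supports constrained-bin burden analyses.
#'
#' @param calls annotated case DNM calls.
#' @param bins GRanges from [generateGnocchiBins()].
#' @param geneModels a [GeneModelSet-class].
#' @param mode "genic" or "intergenic".
#' @param singleAssignment single-assignment bin-to-gene mapping.
#' @param caddMin optional CADD cutoff restricting qualifying DNMs.
#' @param gnocchiMin optional Gnocchi cutoff restricting the bin universe.
#' @param rescaleBeta rescale beta to unit mean over the analyzed universe.
#' @param universeSize declared number of tests for correction.
#' @return data.frame like [runPointTests()], test_family
#'   "segment_genic"/"segment_intergenic", plus n_bins per gene.
#' @export
runSegmentTest <- function(calls, bins, geneModels,
                           mode = c("genic", "intergenic"),
                           singleAssignment = FALSE, caddMin = NULL,
                           gnocchiMin = NULL, rescaleBeta = TRUE,
                           universeSize = 20000L) {
  mode <- match.arg(mode)
  flagWanted <- if (mode == "genic") "genic_noncoding" else "intergenic"
  ncCalls <- calls[calls$region_class %in%
    (if (mode == "genic") .GENIC_NONCODING_CLASSES else "intergenic"), ,
    drop = FALSE]
  if (!is.null(caddMin))
    ncCalls <- ncCalls[!is.na(ncCalls$cadd) & ncCalls$cadd >= caddMin, ,
                       drop = FALSE]
  universe <- which(S4Vectors::mcols(bins)$region_flag == flagWanted)
  if (!is.null(gnocchiMin))
    universe <- universe[S4Vectors::mcols(bins)$gnocchi[universe] > gnocchiMin]
  if (!length(universe)) stop("empty bin universe", call. = FALSE)
  ubins <- bins[universe]
  background <- computeBackground(ncCalls, ubins)
  beta <- S4Vectors::mcols(ubins)$beta
  if (rescaleBeta) beta <- beta / mean(beta)
  mapping <- assignBinsToGenes(bins, geneModels, mode,
                               singleAssignment = singleAssignment)
  mapping <- mapping[mapping$bin_index %in% universe, , drop = FALSE]
  if (!nrow(mapping)) {
    message("runSegmentTest: no gene has assigned bins")
    return(data.frame())
  }
  localIdx <- match(mapping$bin_index, universe)
  expBin <- expectedBinCount(background, beta)
  pts <- GenomicRanges::GRanges(ncCalls$chrom,
                                IRanges::IRanges(ncCalls$pos, width = 1L))
  cnt <- GenomicRanges::countOverlaps(ubins, pts, ignore.strand = TRUE)
  genes <- sort(unique(mapping$gene_id))
  observed <- vapply(split(cnt[localIdx], mapping$gene_id)[genes], sum,
                     numeric(1))
  expected <- vapply(split(expBin[localIdx], mapping$gene_id)[genes], sum,
                     numeric(1))
  nb <- vapply(split(localIdx, mapping$gene_id)[genes], length, numeric(1))
  p <- poissonCaseOnly(as.integer(observed), expected)
  corr <- correctMultiple(p, m = max(universeSize, length(p)))
  data.frame(gene_id = genes,
             test_family = paste0("segment_", mode),
             observed = as.integer(observed), expected = expected,
             n_bins = as.integer(nb), p_value = p,
             p_bonferroni = corr$p_bonferroni,
             bonferroni_sig = corr$bonferroni_sig,
             q_fdr = corr$q_fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}
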