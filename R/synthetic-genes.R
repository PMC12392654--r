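# Synthetic gene models: non-overlapping multi-exon genes packed onto the
# reference, each coding gene with UTRs and a CDS of length divisible by 3.

# Map a transcript-coordinate interval [from, to] (1-based along the spliced
# exons, 5'->3') to genomic IRanges, given genomically sorted exons.
.txToGenomic <- function(exons, strand, from, to) {
  w <- IRanges::width(exons)
  if (strand == "-") exons <- rev(exons)  # tx order = right-to-left
  w <- IRanges::width(exons)
  cw <- cumsum(w)
  first <- findInterval(from - 1L, cw) + 1L
  last <- findInterval(to - 1L, cw) + 1L
  pieces <- lapply(first:last, function(i) {
    lo <- if (i == 1L) 1L else cw[i - 1L] + 1L
    a <- max(from, lo) - lo + 1L   # offset within exon i, tx orientation
    b <- min(to, cw[i]) - lo + 1L
    s <- BiocGenerics::start(exons)[i]; e <- BiocGenerics::end(exons)[i]
    if (strand == "+") IRanges::IRanges(s + a - 1L, s + b - 1L)
    else IRanges::IRanges(e - b + 1L, e - a + 1L)
  })
  IRanges::reduce(do.call(c, pieces))
}

#' Generate non-overlapping synthetic gene models
#'
#' Packs `nGenes` genes onto the reference without overlapping footprints
#' (transcript span plus flank). Every gene has >= 2 exons; coding genes get
#' 5'/3' UTRs and a CDS whose length is divisible by 3; a small fraction are
#' ncRNA genes without a CDS. A configurable number of coding genes receive
#' HLA/MUC-prefixed ids to exercise the difficult-region blacklist filter.
#'
#' @param config a [SimConfig-class].
#' @param reference DNAStringSet from [generateReference()].
#' @return A [GeneModelSet-class].
#' @export
generateGeneModels <- function(config, reference) {
  stopifnot(is(config, "SimConfig"))
  si <- .refSeqinfo(reference)
  .withStageSeed(config@seed, "genes", {
    n <- config@nGenes
    nNc <- round(n * config@ncRnaFraction)
    isCoding <- rep(TRUE, n)
    if (nNc > 0) isCoding[sample.int(n, nNc)] <- FALSE
    chromOf <- rep(seq_len(config@nChromosomes), length.out = n)
    ids <- sprintf("G%04d", seq_len(n))
    nBl <- min(config@nBlacklistGenes, sum(isCoding))
    if (nBl > 0) {
      bl <- sample(which(isCoding), nBl)
      ids[bl] <- paste0(rep(c("HLA", "MUC"), length.out = nBl), "_", ids[bl])
    }

    exL <- vector("list", n); cdsL <- vector("list", n)
    txStart <- txEnd <- integer(n); strand <- character(n)
    cursor <- rep(config@flankBp, config@nChromosomes)
    for (i in seq_len(n)) {
      ch <- chromOf[i]
      nEx <- sample(2:6, 1L)
      exW <- sample(80:300, nEx, replace = TRUE)
      inW <- if (nEx > 1L) sample(200:1500, nEx - 1L, replace = TRUE) else integer(0)
      txLen <- sum(exW) + sum(inW)
      gap <- sample(1000:5000, 1L)
      s <- cursor[ch] + gap
      e <- s + txLen - 1L
      if (e + config@flankBp > config@chromLength)
        stop(sprintf(paste0("infeasible packing: gene %d of %d does not fit on %s ",
                            "(need %d bp past position %d)"),
                     i, n, names(reference)[ch], e + config@flankBp - config@chromLength,
                     config@chromLength), call. = FALSE)
      cursor[ch] <- e + config@flankBp
      exStart <- s + c(0L, cumsum(exW[-nEx] + inW))
      ex <- IRanges::IRanges(exStart, width = exW)
      str <- sample(c("+", "-"), 1L)
      cd <- IRanges::IRanges()
      if (isCoding[i]) {
        E <- sum(exW)
        u5 <- sample(50:250, 1L); u3 <- sample(100:400, 1L)
        u5 <- min(u5, max(0L, (E - 150L) %/% 2L))
        u3 <- min(u3, E - 150L - u5)
        L <- E - u5 - u3; L <- L - L %% 3L
        cd <- .txToGenomic(ex, str, u5 + 1L, u5 + L)
      }
      exL[[i]] <- ex; cdsL[[i]] <- cd
      txStart[i] <- s; txEnd[i] <- e; strand[i] <- str
    }
    chromNames <- names(reference)[chromOf]
    genes <- GenomicRanges::GRanges(chromNames,
                                    IRanges::IRanges(txStart, txEnd),
                                    strand = strand, seqinfo = si)
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = ids, is_coding = isCoding,
      coding_length = vapply(cdsL, function(x) sum(IRanges::width(x)), integer(1)),
      pLI = round(runif(n), 4),
      noncoding_functional_length = NA_integer_,
      intergenic_functional_length = NA_integer_)
    mkGRL <- function(lst) {
      grl <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i)
        GenomicRanges::GRanges(rep(chromNames[i], length(lst[[i]])), lst[[i]],
                               strand = rep(strand[i], length(lst[[i]])),
                               seqinfo = si)))
      names(grl) <- ids
      grl
    }
    new("GeneModelSet", genes = genes, exons = mkGRL(exL), cds = mkGRL(cdsL),
        flank = config@flankBp)
  })
}

#' Write ATG/stop codons into the reference at CDS boundaries
#'
#' The raw reference is random sequence, so coding genes would not begin with
#' a start codon nor end with a stop. This rewrites the first CDS codon to
#' ATG and the last to TAA (strand-aware), so that startloss/stoploss
#' consequences are well defined.
#'
#' @param reference DNAStringSet.
#' @param geneModels a [GeneModelSet-class].
#' @return the modified DNAStringSet.
#' @export
imprintGeneSignals <- function(reference, geneModels) {
  edits <- list()
  g <- geneModels@genes
  for (i in seq_along(g)) {
    cd <- geneModels@cds[[i]]
    if (!length(cd)) next
    str <- as.character(BiocGenerics::strand(g))[i]
    pos <- unlist(lapply(seq_along(cd), function(j)
      seq(BiocGenerics::start(cd)[j], BiocGenerics::end(cd)[j])))
    if (str == "-") pos <- rev(pos)          # tx order 5'->3'
    txBases <- c("A", "T", "G", rep(NA, length(pos) - 6L), "T", "A", "A")
    keep <- !is.na(txBases)
    b <- txBases[keep]; p <- pos[keep]
    if (str == "-") b <- chartr("ACGT", "TGCA", b)
    edits[[length(edits) + 1L]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(g))[i], pos = p, base = b)
  }
  if (!length(edits)) return(reference)
  ed <- do.call(rbind, edits)
  for (ch in unique(ed$chrom)) {
    sel <- ed[ed$chrom == ch, ]
    reference[[ch]] <- Biostrings::replaceLetterAt(
      reference[[ch]], sel$pos, paste(sel$base, collapse = ""))
  }
  reference
}

#' Write gene models as a refFlat-like tab-separated table
#'
#' @param geneModels a [GeneModelSet-class].
#' @param path output file.
#' @export
writeGeneModels <- function(geneModels, path) {
  g <- geneModels@genes
  fmt <- function(grl, f) vapply(seq_along(g), function(i)
    paste(f(IRanges::ranges(grl[[i]])), collapse = ","), character(1))
  df <- data.frame(
    gene_id = g$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    strand = as.character(BiocGenerics::strand(g)),
    tx_start = BiocGenerics::start(g), tx_end = BiocGenerics::end(g),
    exon_starts = fmt(geneModels@exons, BiocGenerics::start),
    exon_ends = fmt(geneModels@exons, BiocGenerics::end),
    cds_starts = fmt(geneModels@cds, BiocGenerics::start),
    cds_ends = fmt(geneModels@cds, BiocGenerics::end),
    pLI = g$pLI)
  writeTsv(df, path, "gene_models")
}
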