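# Region classification, coding consequences, nearest-gene assignment and
# score attachment for DNM calls.

.REGION_PRECEDENCE <- c(exonic = 1, splicing = 2, ncRNA_exonic = 3,
                        ncRNA_splicing = 3, UTR5 = 4, UTR3 = 4,
                        intronic = 5, ncRNA_intronic = 6,
                        upstream = 7, downstream = 7, intergenic = 99)

# 2 bp intron-side windows flanking each exon (canonical splice dinucleotides).
.spliceRanges <- function(exons, tx) {
  if (length(exons) < 1L) return(IRanges::IRanges())
  ex <- IRanges::ranges(exons)
  left <- IRanges::IRanges(BiocGenerics::start(ex) - 2L, BiocGenerics::start(ex) - 1L)
  right <- IRanges::IRanges(BiocGenerics::end(ex) + 1L, BiocGenerics::end(ex) + 2L)
  sp <- c(left, right)
  # keep only windows inside the transcript (i.e., intron side, not flanks)
  sp <- IRanges::intersect(IRanges::reduce(sp),
                           IRanges::setdiff(IRanges::ranges(tx), ex))
  sp
}

# Build one labeled annotation track per gene model set (GRanges with
# mcols gene_id, class, precedence). Per gene, a class code is painted over
# the footprint in increasing precedence (later paints win), then run-length
# encoded into intervals; plain integer arithmetic keeps this fast.
.CLASS_CODES <- c(upstream = 1L, downstream = 2L, ncRNA_intronic = 3L,
                  intronic = 4L, UTR5 = 5L, UTR3 = 6L, ncRNA_exonic = 7L,
                  ncRNA_splicing = 8L, splicing = 9L, exonic = 10L)

.annotationTrack <- function(geneModels) {
  g <- geneModels@genes
  chroms <- as.character(GenomeInfoDb::seqnames(g))
  strands <- as.character(BiocGenerics::strand(g))
  si <- GenomeInfoDb::seqinfo(g)
  lens <- GenomeInfoDb::seqlengths(si)
  fl <- geneModels@flank
  acc <- list(chrom = vector("list", length(g)),
              start = vector("list", length(g)),
              end = vector("list", length(g)),
              gid = vector("list", length(g)),
              cls = vector("list", length(g)))
  codeNames <- names(.CLASS_CODES)
  gS <- BiocGenerics::start(g); gE <- BiocGenerics::end(g)
  exSl <- as.list(BiocGenerics::start(geneModels@exons))
  exEl <- as.list(BiocGenerics::end(geneModels@exons))
  cdSl <- as.list(BiocGenerics::start(geneModels@cds))
  cdEl <- as.list(BiocGenerics::end(geneModels@cds))
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]; ch <- chroms[i]; str <- strands[i]
    txS <- gS[i]; txE <- gE[i]
    exS <- exSl[[i]]; exE <- exEl[[i]]
    cdS <- cdSl[[i]]; cdE <- cdEl[[i]]
    coding <- g$is_coding[i] && length(cdS) > 0L
    fpS <- max(1L, txS - fl); fpE <- min(lens[[ch]], txE + fl)
    off <- fpS - 1L                      # genomic pos = off + index
    v <- integer(fpE - fpS + 1L)
    paint <- function(s, e, code) {
      s <- pmax(s, fpS); e <- pmin(e, fpE)
      keep <- s <= e
      for (k in which(keep)) v[(s[k] - off):(e[k] - off)] <<- code
    }
    # flanks (strand-aware), then transcript interior
    if (str == "+") {
      paint(fpS, txS - 1L, .CLASS_CODES[["upstream"]])
      paint(txE + 1L, fpE, .CLASS_CODES[["downstream"]])
    } else {
      paint(txE + 1L, fpE, .CLASS_CODES[["upstream"]])
      paint(fpS, txS - 1L, .CLASS_CODES[["downstream"]])
    }
    paint(txS, txE,
          .CLASS_CODES[[if (coding) "intronic" else "ncRNA_intronic"]])
    if (coding) {
      cdL <- min(cdS); cdR <- max(cdE)
      lab5 <- if (str == "+") "UTR5" else "UTR3"
      lab3 <- if (str == "+") "UTR3" else "UTR5"
      paint(exS, pmin(exE, cdL - 1L), .CLASS_CODES[[lab5]])
      paint(pmax(exS, cdR + 1L), exE, .CLASS_CODES[[lab3]])
    } else {
      paint(exS, exE, .CLASS_CODES[["ncRNA_exonic"]])
    }
    # canonical splice dinucleotides: 2 bp intron-side of each exon edge
    spCode <- .CLASS_CODES[[if (coding) "splicing" else "ncRNA_splicing"]]
    intronCode <- .CLASS_CODES[[if (coding) "intronic" else "ncRNA_intronic"]]
    spPos <- c(rbind(exS - 2L, exS - 1L, exE + 1L, exE + 2L))
    spPos <- spPos[spPos >= txS & spPos <= txE]
    spPos <- spPos[v[spPos - off] == intronCode]
    v[spPos - off] <- spCode
    if (coding) paint(cdS, cdE, .CLASS_CODES[["exonic"]])
    r <- rle(v)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    keep <- r$values > 0L
    acc$chrom[[i]] <- rep(ch, sum(keep))
    acc$start[[i]] <- startIdx[keep] + off
    acc$end[[i]] <- endIdx[keep] + off
    acc$gid[[i]] <- rep(gid, sum(keep))
    acc$cls[[i]] <- codeNames[r$values[keep]]
  }
  chrom <- unlist(acc$chrom); cls <- unlist(acc$cls)
  track <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(unlist(acc$start), unlist(acc$end)), seqinfo = si)
  S4Vectors::mcols(track) <- S4Vectors::DataFrame(
    gene_id = unlist(acc$gid), class = cls,
    precedence = unname(.REGION_PRECEDENCE[cls]))
  track
}

#' Classify each variant into a region class and assign its gene
#'
#' Precedence: exonic > splicing > ncRNA exonic/splicing > UTR5/UTR3 >
#' intronic > ncRNA intronic > upstream/downstream > intergenic. Splicing is
#' the 2 bp intron side of each exon boundary; upstream/downstream is the
#' flank outside the transcript (strand-aware). When several genes could
#' claim a variant, the highest-precedence class wins, ties broken by the
#' lexicographically smaller gene id. Intergenic variants get gene_id NA.
#'
#' @param calls data.frame with chrom, pos columns.
#' @param geneModels a [GeneModelSet-class].
#' @return the input with `gene_id` and `region_class` columns appended.
#' @export
classifyRegion <- function(calls, geneModels) {
  si <- GenomeInfoDb::seqinfo(geneModels@genes)
  lens <- GenomeInfoDb::seqlengths(si)
  bad <- !(calls$chrom %in% names(lens)) | calls$pos < 1L |
    calls$pos > lens[calls$chrom]
  if (any(bad))
    stop(sum(bad), " variant(s) beyond chromosome bounds", call. = FALSE)
  track <- .annotationTrack(geneModels)
  pts <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, width = 1L),
                                seqinfo = si)
  hits <- GenomicRanges::findOverlaps(pts, track, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ord <- order(q, S4Vectors::mcols(track)$precedence[s],
               S4Vectors::mcols(track)$gene_id[s])
  q <- q[ord]; s <- s[ord]
  first <- !duplicated(q)
  gene <- rep(NA_character_, nrow(calls))
  cls <- rep("intergenic", nrow(calls))
  gene[q[first]] <- S4Vectors::mcols(track)$gene_id[s[first]]
  cls[q[first]] <- S4Vectors::mcols(track)$class[s[first]]
  calls$gene_id <- gene
  calls$region_class <- cls
  calls
}

# Spliced CDS sequence (5'->3') and a map from genomic position to CDS offset.
.cdsContext <- function(geneModels, reference, geneIdx) {
  g <- geneModels@genes[geneIdx]
  cd <- geneModels@cds[[geneIdx]]
  str <- as.character(BiocGenerics::strand(g))
  ch <- as.character(GenomeInfoDb::seqnames(g))
  pos <- unlist(lapply(seq_along(cd), function(j)
    seq(BiocGenerics::start(cd)[j], BiocGenerics::end(cd)[j])))
  seq <- paste(.refSeqAt(reference, rep(ch, length(cd)),
                         BiocGenerics::start(cd), IRanges::width(cd)),
               collapse = "")
  if (str == "-") {
    pos <- rev(pos)
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  list(seq = seq, pos = pos, strand = str, chrom = ch)
}

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Coding consequence of exonic and splicing calls
#'
#' SNVs are translated through the genetic code with strand handling:
#' a changed first codon that was the ATG start is `startloss`; a new stop
#' codon is `stopgain`; a changed terminal stop codon is `stoploss`; else
#' `missense` or `synonymous`. Indels whose length difference is not a
#' multiple of 3 are `frameshift_insertion`/`frameshift_deletion`, otherwise
#' `nonframeshift_indel`. Splicing-region calls are `splicing`. The derived
#' `is_LGD` flag marks frameshift, startloss, stopgain, stoploss and
#' splicing. Genes whose CDS length is not divisible by 3 yield `other`.
#'
#' @param calls data.frame with chrom, pos, ref, alt, gene_id,
#'   region_class columns (exonic/splicing rows are annotated, all other
#'   rows get NA consequence).
#' @param geneModels a [GeneModelSet-class].
#' @param reference DNAStringSet.
#' @return the input with `consequence` and `is_LGD` columns appended.
#' @export
codingConsequence <- function(calls, geneModels, reference) {
  cons <- rep(NA_character_, nrow(calls))
  idxSplice <- which(calls$region_class == "splicing")
  cons[idxSplice] <- "splicing"
  idxEx <- which(calls$region_class == "exonic")
  ctxCache <- list()
  for (i in idxEx) {
    gi <- match(calls$gene_id[i], geneIds(geneModels))
    if (is.na(gi)) { cons[i] <- "other"; next }
    key <- as.character(gi)
    if (is.null(ctxCache[[key]]))
      ctxCache[[key]] <- .cdsContext(geneModels, reference, gi)
    ctx <- ctxCache[[key]]
    ref <- calls$ref[i]; alt <- calls$alt[i]
    if (nchar(ref) != nchar(alt)) {
      d <- nchar(alt) - nchar(ref)
      cons[i] <- if (d %% 3L != 0L) {
        if (d > 0L) "frameshift_insertion" else "frameshift_deletion"
      } else "nonframeshift_indel"
      next
    }
    if (nchar(ref) != 1L) { cons[i] <- "other"; next }
    if (nchar(ctx$seq) %% 3L != 0L) { cons[i] <- "other"; next }
    off <- match(calls$pos[i], ctx$pos)
    if (is.na(off)) { cons[i] <- "other"; next }
    base <- if (ctx$strand == "-") chartr("ACGT", "TGCA", alt) else alt
    codonIdx <- (off - 1L) %/% 3L + 1L
    cstart <- (codonIdx - 1L) * 3L + 1L
    refCodon <- substr(ctx$seq, cstart, cstart + 2L)
    inCodon <- off - cstart + 1L
    altCodon <- refCodon
    substr(altCodon, inCodon, inCodon) <- base
    refAa <- .translateCodon(refCodon); altAa <- .translateCodon(altCodon)
    nCodons <- nchar(ctx$seq) %/% 3L
    cons[i] <-
      if (codonIdx == 1L && refCodon == "ATG" && altCodon != "ATG") "startloss"
      else if (codonIdx == nCodons && identical(refAa, "*") &&
               !identical(altAa, "*")) "stoploss"
      else if (identical(altAa, "*") && !identical(refAa, "*")) "stopgain"
      else if (identical(refAa, altAa)) "synonymous"
      else "missense"
  }
  calls$consequence <- cons
  calls$is_LGD <- !is.na(cons) & cons %in% c(
    "frameshift_deletion", "frameshift_insertion", "startloss",
    "stopgain", "stoploss", "splicing")
  calls
}

#' Assign intergenic variants to their nearest gene
#'
#' Distance is measured from the variant position to the closest gene
#' footprint boundary; exact ties go to the lexicographically smaller gene
#' id. Variants inside a footprint are rejected (they are not intergenic);
#' chromosomes without genes leave the variant unassigned (NA, logged).
#'
#' @param calls data.frame with chrom, pos, region_class columns.
#' @param geneModels a [GeneModelSet-class].
#' @return the input with a `nearest_gene` column appended (non-NA only for
#'   intergenic rows).
#' @export
assignNearestGene <- function(calls, geneModels) {
  fp <- footprints(geneModels)
  idx <- which(calls$region_class == "intergenic")
  nearest <- rep(NA_character_, nrow(calls))
  if (length(idx)) {
    pts <- GenomicRanges::GRanges(calls$chrom[idx],
                                  IRanges::IRanges(calls$pos[idx], width = 1L),
                                  seqinfo = GenomeInfoDb::seqinfo(fp))
    if (any(IRanges::overlapsAny(pts, fp, ignore.strand = TRUE)))
      stop("variant inside a gene footprint cannot be intergenic", call. = FALSE)
    hits <- GenomicRanges::distanceToNearest(pts, fp, select = "all",
                                             ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      d <- S4Vectors::mcols(hits)$distance
      gid <- geneModels@genes$gene_id[s]
      ord <- order(q, d, gid)
      q <- q[ord]; gid <- gid[ord]
      first <- !duplicated(q)
      nearest[idx[q[first]]] <- gid[first]
    }
    nMissing <- sum(is.na(nearest[idx]))
    if (nMissing)
      message("assignNearestGene: ", nMissing,
              " intergenic variant(s) on gene-free chromosomes left unassigned")
  }
  calls$nearest_gene <- nearest
  calls
}

#' Attach functional scores and threshold flags to calls
#'
#' Adds per-variant CADD-like, FATHMM-like and SpliceAI-like scores (missing
#' stays missing, never imputed) and the convenience flags `cadd15`
#' (score >= 15, inclusive), `fathmm_patho` (score > 0.5, strict) and
#' `spliceai_high` (delta >= 0.8, inclusive).
#'
#' @param calls data.frame with chrom, pos columns.
#' @param scores from [generateSiteScores()] (or any list with the same
#'   shape).
#' @return the input with score and flag columns appended.
#' @export
attachScores <- function(calls, scores) {
  calls$cadd <- .scoreAt(scores, calls$chrom, calls$pos, "cadd")
  calls$fathmm <- .scoreAt(scores, calls$chrom, calls$pos, "fathmm")
  calls$spliceai <- .scoreAt(scores, calls$chrom, calls$pos, "spliceai")
  calls$cadd15 <- !is.na(calls$cadd) & calls$cadd >= 15
  calls$fathmm_patho <- !is.na(calls$fathmm) & calls$fathmm > 0.5
  calls$spliceai_high <- !is.na(calls$spliceai) & calls$spliceai >= 0.8
  calls
}

# Canonical splice positions of one gene from plain exon/tx coordinates:
# 2 bp intron-side of each exon edge, inside the transcript, not exonic.
.splicePositions <- function(exS, exE, txS, txE) {
  if (!length(exS)) return(integer(0))
  p <- unique(c(rbind(exS - 2L, exS - 1L, exE + 1L, exE + 2L)))
  p <- p[p >= txS & p <= txE]
  if (!length(p)) return(integer(0))
  inExon <- vapply(p, function(x) any(x >= exS & x <= exE), logical(1))
  p[!inExon]
}

#' Noncoding functional length per gene
#'
#' Counts, for each gene, the positions of its noncoding footprint
#' (footprint minus CDS and canonical splice dinucleotides) whose
#' deleteriousness score is >= `threshold`. This is the effective mutational
#' target of the CADD-filtered point-based test and is stored on the model
#' as `noncoding_functional_length`.
#'
#' @param geneModels a [GeneModelSet-class].
#' @param scores from [generateSiteScores()].
#' @param threshold score cutoff (default 15).
#' @return the updated [GeneModelSet-class].
#' @export
noncodingFunctionalLength <- function(geneModels, scores, threshold = 15) {
  g <- geneModels@genes
  chroms <- as.character(GenomeInfoDb::seqnames(g))
  cum <- lapply(scores, function(s) cumsum(s$cadd >= threshold))
  fp <- footprints(geneModels)
  fpS <- BiocGenerics::start(fp); fpE <- BiocGenerics::end(fp)
  gS <- BiocGenerics::start(g); gE <- BiocGenerics::end(g)
  exSl <- as.list(BiocGenerics::start(geneModels@exons))
  exEl <- as.list(BiocGenerics::end(geneModels@exons))
  cdSl <- as.list(BiocGenerics::start(geneModels@cds))
  cdEl <- as.list(BiocGenerics::end(geneModels@cds))
  hiIn <- function(cs, s, e) sum(cs[e] - ifelse(s > 1L, cs[s - 1L], 0))
  out <- integer(length(g))
  for (i in seq_along(g)) {
    cs <- cum[[chroms[i]]]
    if (is.null(cs)) stop("no score coverage for chromosome ", chroms[i],
                          call. = FALSE)
    if (fpE[i] > length(cs))
      stop("score track does not cover the footprint of ",
           g$gene_id[i], call. = FALSE)
    # footprint minus CDS minus canonical splice dinucleotides
    n <- hiIn(cs, fpS[i], fpE[i])
    if (length(cdSl[[i]])) n <- n - hiIn(cs, cdSl[[i]], cdEl[[i]])
    if (g$is_coding[i]) {
      sp <- .splicePositions(exSl[[i]], exEl[[i]], gS[i], gE[i])
      if (length(sp)) n <- n - sum(cs[sp] - cs[sp - 1L])
    }
    out[i] <- n
  }
  geneModels@genes$noncoding_functional_length <- out
  geneModels
}

# Partition of intergenic space by nearest gene (genes non-overlapping;
# boundaries at midpoints between adjacent footprints).
.intergenicTerritory <- function(geneModels) {
  fp <- footprints(geneModels)
  si <- GenomeInfoDb::seqinfo(fp)
  out <- list()
  for (ch in GenomeInfoDb::seqlevels(fp)) {
    sel <- which(as.character(GenomeInfoDb::seqnames(fp)) == ch)
    if (!length(sel)) next
    ord <- sel[order(BiocGenerics::start(fp)[sel])]
    st <- BiocGenerics::start(fp)[ord]; en <- BiocGenerics::end(fp)[ord]
    gid <- geneModels@genes$gene_id[ord]
    L <- GenomeInfoDb::seqlengths(si)[ch]
    segs <- list()
    if (st[1] > 1L)
      segs[[length(segs) + 1L]] <- data.frame(start = 1L, end = st[1] - 1L,
                                              gene = gid[1])
    if (length(ord) > 1L) for (k in seq_len(length(ord) - 1L)) {
      a <- en[k] + 1L; b <- st[k + 1L] - 1L
      if (a > b) next
      mid <- (a + b) %/% 2L
      # tie position equidistant to both: goes to lexicographically smaller id
      gLeft <- gid[k]; gRight <- gid[k + 1L]
      segs[[length(segs) + 1L]] <- data.frame(start = a, end = mid, gene = gLeft)
      if (mid + 1L <= b)
        segs[[length(segs) + 1L]] <- data.frame(start = mid + 1L, end = b,
                                                gene = gRight)
    }
    if (en[length(ord)] < L)
      segs[[length(segs) + 1L]] <- data.frame(start = en[length(ord)] + 1L,
                                              end = L, gene = gid[length(ord)])
    if (length(segs)) {
      df <- do.call(rbind, segs); df$chrom <- ch
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, out)
}

#' Intergenic functional length per gene
#'
#' Counts the intergenic positions (nearest-gene territory, midpoint
#' boundaries between adjacent footprints) with score >= `threshold`, the
#' expected-model target for the intergenic point-based test; stored as
#' `intergenic_functional_length`.
#'
#' @inheritParams noncodingFunctionalLength
#' @return the updated [GeneModelSet-class].
#' @export
intergenicFunctionalLength <- function(geneModels, scores, threshold = 15) {
  terr <- .intergenicTerritory(geneModels)
  g <- geneModels@genes
  cum <- lapply(scores, function(s) cumsum(s$cadd >= threshold))
  out <- setNames(integer(length(g)), g$gene_id)
  for (k in seq_len(nrow(terr))) {
    cs <- cum[[terr$chrom[k]]]
    en <- min(terr$end[k], length(cs)); st <- terr$start[k]
    hi <- cs[en] - if (st > 1L) cs[st - 1L] else 0
    out[terr$gene[k]] <- out[terr$gene[k]] + hi
  }
  geneModels@genes$intergenic_functional_length <- unname(out)
  geneModels
}

#' Annotate DNM calls end to end
#'
#' Region classification, coding consequence, nearest-gene assignment for
#' intergenic calls, and score attachment, in that order.
#'
#' @param calls data.frame with chrom, pos, ref, alt columns.
#' @param geneModels a [GeneModelSet-class].
#' @param reference DNAStringSet.
#' @param scores optional score track.
#' @return the fully annotated data.frame.
#' @export
annotateCalls <- function(calls, geneModels, reference, scores = NULL) {
  calls <- classifyRegion(calls, geneModels)
  calls <- codingConsequence(calls, geneModels, reference)
  calls <- assignNearestGene(calls, geneModels)
  if (!is.null(scores) && length(scores)) calls <- attachScores(calls, scores)
  calls
}
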