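# Shared fixtures: a memoized small synthetic study and a hand-built
# micro gene model with fully known coordinates and codons.

.fixtures <- new.env(parent = emptyenv())

smallConfig <- function() {
  simConfig(seed = 11L, nChromosomes = 1L, chromLength = 300000L,
            nGenes = 30L, nCaseTrios = 40L, nControlTrios = 40L,
            dnmRate = 25, codingDnmsPerChild = 1.2, decoysPerType = 4L,
            inheritedHetsPerChild = 3)
}

smallStudy <- function() {
  if (is.null(.fixtures$small)) {
    st <- simulateStudy(smallConfig())
    gm <- noncodingFunctionalLength(st@genes, st@scores)
    gm <- intergenicFunctionalLength(gm, st@scores)
    .fixtures$small <- list(study = st, gm = gm)
  }
  .fixtures$small
}

smallCalled <- function() {
  if (is.null(.fixtures$called)) {
    fx <- smallStudy()
    st <- fx$study
    .fixtures$called <- callDnms(cohortRecords(st@cohort), fx$gm,
                                 st@reference, mask = st@mask,
                                 afTable = st@afTable, scores = st@scores)
  }
  .fixtures$called
}

# A 600 bp chromosome with one plus-strand coding gene of exactly known
# structure: tx 101-230, exons 101-130 and 171-230, 6 bp UTRs, 78 bp CDS
# (codons ATG AAA TAC CAT TGG GGAx20 TAA), plus an ncRNA gene at 402-471.
microModel <- function() {
  if (!is.null(.fixtures$micro)) return(.fixtures$micro)
  seqv <- rep("A", 600)
  codons <- c("ATG", "AAA", "TAC", "CAT", "TGG", rep("GGA", 20), "TAA")
  cdsSeq <- strsplit(paste(codons, collapse = ""), "")[[1]]
  stopifnot(length(cdsSeq) == 78L)
  seqv[107:130] <- cdsSeq[1:24]
  seqv[171:224] <- cdsSeq[25:78]
  ref <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(ref) <- "chrT"
  si <- GenomeInfoDb::Seqinfo("chrT", 600L)
  genes <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(101L, 402L),
                                                           c(230L, 471L)),
                                  strand = c("+", "+"), seqinfo = si)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = c("PG1", "AG2"), is_coding = c(TRUE, FALSE),
    coding_length = c(78L, 0L), pLI = c(0.99, 0.1),
    noncoding_functional_length = NA_integer_,
    intergenic_functional_length = NA_integer_)
  exons <- GenomicRanges::GRangesList(
    PG1 = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(101L, 171L), c(130L, 230L)), strand = "+",
      seqinfo = si),
    AG2 = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(402L, 442L), c(431L, 471L)), strand = "+",
      seqinfo = si))
  cds <- GenomicRanges::GRangesList(
    PG1 = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(107L, 171L), c(130L, 224L)), strand = "+",
      seqinfo = si),
    AG2 = GenomicRanges::GRanges(seqinfo = si))
  gm <- new("GeneModelSet", genes = genes, exons = exons, cds = cds,
            flank = 50L)
  .fixtures$micro <- list(ref = ref, gm = gm)
  .fixtures$micro
}

# one-row call table for annotator unit tests
callRow <- function(pos, ref = "A", alt = "G", chrom = "chrT") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
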