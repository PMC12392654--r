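# Region classification, coding consequences, nearest gene, score flags.

test_that("region classes follow the precedence and boundary conventions", {
  fx <- microModel()
  cls <- function(pos) {
    out <- classifyRegion(callRow(pos), fx$gm)
    c(out$gene_id, out$region_class)
  }
  expect_equal(cls(110L), c("PG1", "exonic"))        # inside CDS
  expect_equal(cls(103L), c("PG1", "UTR5"))
  expect_equal(cls(227L), c("PG1", "UTR3"))
  expect_equal(cls(131L), c("PG1", "splicing"))      # 1 bp into intron
  expect_equal(cls(132L), c("PG1", "splicing"))      # 2 bp into intron
  expect_equal(cls(133L), c("PG1", "intronic"))      # 3 bp into intron
  expect_equal(cls(80L), c("PG1", "upstream"))       # + strand left flank
  expect_equal(cls(240L), c("PG1", "downstream"))
  expect_equal(cls(410L), c("AG2", "ncRNA_exonic"))
  expect_equal(cls(433L), c("AG2", "ncRNA_splicing"))
  expect_equal(cls(436L), c("AG2", "ncRNA_intronic"))
  out <- classifyRegion(callRow(10L), fx$gm)
  expect_true(is.na(out$gene_id))
  expect_equal(out$region_class, "intergenic")
  expect_error(classifyRegion(callRow(10000L), fx$gm), "beyond chromosome")
})

test_that("every variant gets exactly one class, matching an interval oracle", {
  fx <- smallStudy()
  gm <- fx$gm
  set.seed(7)
  pos <- sample.int(300000L, 10000L)
  calls <- data.frame(chrom = "chr1", pos = pos)
  got <- classifyRegion(calls, gm)
  expect_false(any(is.na(got$region_class)))
  # independent IRanges-based oracle on a subsample
  sub <- sample.int(nrow(got), 400L)
  fp <- footprints(gm)
  gt <- geneTable(gm)
  for (k in sub) {
    p <- got$pos[k]
    hitsGene <- which(p >= BiocGenerics::start(fp) & p <= BiocGenerics::end(fp))
    if (!length(hitsGene)) { expect_equal(got$region_class[k], "intergenic"); next }
    best <- NULL
    for (i in hitsGene) {
      tx <- IRanges::ranges(gm@genes[i])
      ex <- IRanges::ranges(exonRanges(gm)[[i]])
      cd <- IRanges::ranges(cdsRanges(gm)[[i]])
      inside <- function(ir) length(ir) && any(
        p >= BiocGenerics::start(ir) & p <= BiocGenerics::end(ir))
      sp <- IRanges::intersect(
        IRanges::reduce(c(IRanges::IRanges(BiocGenerics::start(ex) - 2L,
                                           BiocGenerics::start(ex) - 1L),
                          IRanges::IRanges(BiocGenerics::end(ex) + 1L,
                                           BiocGenerics::end(ex) + 2L))),
        IRanges::setdiff(tx, ex))
      coding <- gt$is_coding[i] && length(cd)
      cls <- if (coding && inside(cd)) "exonic"
        else if (coding && inside(sp)) "splicing"
        else if (!coding && inside(ex)) "ncRNA_exonic"
        else if (!coding && inside(sp)) "ncRNA_splicing"
        else if (coding && inside(ex)) {
          if (p < min(BiocGenerics::start(cd))) {
            if (gt$strand[i] == "+") "UTR5" else "UTR3"
          } else if (gt$strand[i] == "+") "UTR3" else "UTR5"
        }
        else if (inside(tx)) { if (coding) "intronic" else "ncRNA_intronic" }
        else {
          left <- p < BiocGenerics::start(tx)
          if ((gt$strand[i] == "+") == left) "upstream" else "downstream"
        }
      cand <- list(gene = gt$gene_id[i], cls = cls,
                   prec = DNMburden:::.REGION_PRECEDENCE[[cls]])
      if (is.null(best) || cand$prec < best$prec ||
          (cand$prec == best$prec && cand$gene < best$gene)) best <- cand
    }
    expect_equal(got$region_class[k], best$cls,
                 label = paste("pos", p))
    expect_equal(got$gene_id[k], best$gene, label = paste("pos", p))
  }
})

test_that("coding consequences follow the genetic code", {
  fx <- microModel()
  csq <- function(pos, ref, alt) {
    calls <- classifyRegion(callRow(pos, ref, alt), fx$gm)
    out <- codingConsequence(calls, fx$gm, fx$ref)
    c(out$consequence, out$is_LGD)
  }
  # codon 2 is AAA (genomic 110-112): third-base A>G keeps Lys
  expect_equal(csq(112L, "A", "G"), c("synonymous", "FALSE"))
  # first-base A>G gives GAA = Glu
  expect_equal(csq(110L, "A", "G"), c("missense", "FALSE"))
  # codon 3 TAC (113-115): C>A gives TAA stop
  expect_equal(csq(115L, "C", "A"), c("stopgain", "TRUE"))
  # start codon ATG (107-109) disrupted
  expect_equal(csq(107L, "A", "G"), c("startloss", "TRUE"))
  # terminal TAA (222-224): A>C gives TCA = Ser
  expect_equal(csq(223L, "A", "C"), c("stoploss", "TRUE"))
  # canonical splice site
  expect_equal(csq(131L, "A", "G"), c("splicing", "TRUE"))
  # 1 bp deletion in CDS
  expect_equal(csq(110L, "AA", "A"), c("frameshift_deletion", "TRUE"))
  # 3 bp insertion in CDS
  expect_equal(csq(110L, "A", "ACCC"), c("nonframeshift_indel", "FALSE"))
})

test_that("reverse-strand consequences equal the mirrored forward construct", {
  fx <- microModel()
  L <- 600L
  refM <- Biostrings::DNAStringSet(Biostrings::reverseComplement(fx$ref[[1]]))
  names(refM) <- "chrT"
  si <- GenomeInfoDb::Seqinfo("chrT", L)
  mirror <- function(gr) {
    ir <- IRanges::IRanges(L - BiocGenerics::end(gr) + 1L,
                           L - BiocGenerics::start(gr) + 1L)
    GenomicRanges::GRanges("chrT", IRanges::IRanges(sort(BiocGenerics::start(ir)),
                                                    sort(BiocGenerics::end(ir))),
                           strand = "-", seqinfo = si)
  }
  genes <- mirror(fx$gm@genes[1])
  S4Vectors::mcols(genes) <- S4Vectors::mcols(fx$gm@genes[1])
  gmM <- new("GeneModelSet", genes = genes,
             exons = GenomicRanges::GRangesList(PG1 = mirror(exonRanges(fx$gm)[["PG1"]])),
             cds = GenomicRanges::GRangesList(PG1 = mirror(cdsRanges(fx$gm)[["PG1"]])),
             flank = 50L)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  for (case in list(list(112L, "A", "G"), list(110L, "A", "G"),
                    list(115L, "C", "A"), list(107L, "A", "G"),
                    list(223L, "A", "C"))) {
    pos <- case[[1]]; ref <- case[[2]]; alt <- case[[3]]
    fwd <- codingConsequence(classifyRegion(callRow(pos, ref, alt), fx$gm),
                             fx$gm, fx$ref)
    rev <- codingConsequence(
      classifyRegion(callRow(L - pos + 1L, comp(ref), comp(alt)), gmM),
      gmM, refM)
    expect_equal(rev$consequence, fwd$consequence, label = paste("pos", pos))
  }
})

test_that("nearest-gene assignment minimizes distance and breaks ties by id", {
  fx <- microModel()
  # PG1 footprint ends at 280, AG2 footprint starts at 352
  near <- function(pos) {
    calls <- classifyRegion(callRow(pos), fx$gm)
    assignNearestGene(calls, fx$gm)$nearest_gene
  }
  expect_equal(near(300L), "PG1")    # 20 vs 52
  expect_equal(near(340L), "AG2")    # 60 vs 12
  expect_equal(near(316L), "AG2")    # exact tie 36/36: smaller id
  inFp <- classifyRegion(callRow(110L), fx$gm)
  inFp$region_class <- "intergenic"  # violates the precondition
  expect_error(assignNearestGene(inFp, fx$gm), "cannot be intergenic")
})

test_that("score threshold flags use the stated inclusivity", {
  sc <- list(chrT = list(cadd = c(15, 14.99, 20), fathmm = c(0.5, 0.51, 0.1),
                         spliceai = c(0.8, 0.79, 0)))
  calls <- data.frame(chrom = "chrT", pos = 1:3)
  out <- attachScores(calls, sc)
  expect_identical(out$cadd15, c(TRUE, FALSE, TRUE))
  expect_identical(out$fathmm_patho, c(FALSE, TRUE, FALSE))
  expect_identical(out$spliceai_high, c(TRUE, FALSE, FALSE))
  # positions without coverage stay missing
  out2 <- attachScores(data.frame(chrom = "chrT", pos = 99L), sc)
  expect_true(is.na(out2$cadd))
  expect_false(out2$cadd15)
})

test_that("footprint partitions into coding and noncoding lengths", {
  fx <- smallStudy()
  gm <- fx$gm
  gt <- geneTable(gm)
  fp <- footprints(gm)
  for (i in c(2L, 9L)) {
    ncAll <- IRanges::setdiff(IRanges::ranges(fp[i]),
                              IRanges::ranges(cdsRanges(gm)[[i]]))
    expect_equal(sum(IRanges::width(ncAll)) + gt$coding_length[i],
                 IRanges::width(fp)[i])
  }
})
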