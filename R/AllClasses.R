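#' Simulation configuration for a synthetic trio study
#'
#' Holds every tunable of the synthetic-cohort generator: genome geometry,
#' gene count, cohort sizes, the genome-wide mean number of de novo mutations
#' (DNMs) per child, per-gene enrichment multipliers for the case cohort,
#' the sequencing-depth model used to fabricate AD/DP/GQ fields, and the
#' number of filter-violating decoy records planted per filter criterion.
#'
#' @slot seed single integer; drives one named pseudo-random stream per
#'   generator stage, so identical configs give byte-identical outputs.
#' @slot nChromosomes,chromLength,nGenes genome geometry (autosome-like
#'   chromosomes only; genes are packed without overlapping footprints).
#' @slot ncRnaFraction fraction of genes generated without a CDS (ncRNA).
#' @slot nCaseTrios,nControlTrios trio counts per cohort arm.
#' @slot dnmRate genome-wide mean DNMs per child (Poisson mean).
#' @slot codingDnmsPerChild mean coding DNMs per child; fixes the scale of
#'   the per-gene mutation-rate table (sum of 2*p_gene over genes).
#' @slot enrichment named numeric; per-gene fold multipliers applied to the
#'   case cohort only (names are gene ids; >= 0).
#' @slot depthMean,depthSize negative-binomial read-depth model (mu, size).
#' @slot inheritedHetsPerChild mean inherited heterozygous background
#'   variants per child (present in one parent; not DNM candidates).
#' @slot decoysPerType low-quality decoy records planted per filter
#'   criterion per cohort, each violating exactly one criterion.
#' @slot indelFraction fraction of planted DNMs that are short indels.
#' @slot caddTailFraction probability that a site's deleteriousness score is
#'   >= 15 (CADD 15 marks roughly the top 1.8% most deleterious variants).
#' @slot gammaShape,gammaScale gamma law for per-1kb-bin expected rare
#'   variant counts (defaults 4, 0.25: mean 1 with realistic heterogeneity).
#' @slot flankBp upstream/downstream flank defining the gene footprint.
#' @slot nBlacklistGenes genes renamed with HLA/MUC prefixes to exercise the
#'   difficult-region blacklist filter (excluded from clean DNM placement).
#' @slot maskWindowsPerChrom,maskWindowBp low-mappability mask geometry
#'   (intergenic windows only).
#' @export
setClass("SimConfig", representation(
  seed = "integer", nChromosomes = "integer", chromLength = "integer",
  nGenes = "integer", ncRnaFraction = "numeric",
  nCaseTrios = "integer", nControlTrios = "integer",
  dnmRate = "numeric", codingDnmsPerChild = "numeric",
  enrichment = "numeric", depthMean = "numeric", depthSize = "numeric",
  inheritedHetsPerChild = "numeric", decoysPerType = "integer",
  indelFraction = "numeric", caddTailFraction = "numeric",
  gammaShape = "numeric", gammaScale = "numeric",
  flankBp = "integer", nBlacklistGenes = "integer",
  maskWindowsPerChrom = "integer", maskWindowBp = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  for (nm in c("seed", "nChromosomes", "chromLength", "nGenes",
               "nCaseTrios", "nControlTrios", "decoysPerType",
               "flankBp", "maskWindowsPerChrom", "maskWindowBp"))
    if (length(slot(object, nm)) != 1L || is.na(slot(object, nm)))
      msg <- c(msg, sprintf("'%s' must be a single non-NA integer", nm))
  if (!length(msg)) {
    if (object@chromLength < 1e4) msg <- c(msg, "chromLength must be >= 10 kb")
    for (nm in c("nChromosomes", "nGenes", "nCaseTrios", "nControlTrios"))
      if (slot(object, nm) <= 0L) msg <- c(msg, sprintf("'%s' must be > 0", nm))
    if (object@dnmRate <= 0) msg <- c(msg, "dnmRate must be > 0")
    if (object@codingDnmsPerChild <= 0 ||
        object@codingDnmsPerChild >= object@dnmRate)
      msg <- c(msg, "codingDnmsPerChild must be in (0, dnmRate)")
    if (any(object@enrichment < 0)) msg <- c(msg, "enrichment multipliers must be >= 0")
    if (length(object@enrichment) && is.null(names(object@enrichment)))
      msg <- c(msg, "enrichment must be named by gene id")
    if (object@ncRnaFraction < 0 || object@ncRnaFraction >= 1)
      msg <- c(msg, "ncRnaFraction must be in [0, 1)")
    if (object@caddTailFraction <= 0 || object@caddTailFraction >= 1)
      msg <- c(msg, "caddTailFraction must be in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Defaults encode the synthetic study conditions: two 3 Mb chromosomes
#' carrying 540 genes, 500 case and 500 control trios, 90 DNMs per child of
#' which 1.27 are coding on average, and a score track whose top 1.8% of
#' sites score >= 15.
#'
#' @param seed integer seed for all generator stages.
#' @param nChromosomes,chromLength,nGenes,ncRnaFraction genome geometry.
#' @param nCaseTrios,nControlTrios cohort sizes.
#' @param dnmRate,codingDnmsPerChild per-child DNM means.
#' @param enrichment named numeric fold multipliers (case cohort only).
#' @param depthMean,depthSize,inheritedHetsPerChild,decoysPerType,
#'   indelFraction,caddTailFraction,gammaShape,gammaScale,flankBp,
#'   nBlacklistGenes,maskWindowsPerChrom,maskWindowBp see class slots.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 30L, chromLength = 200000L,
#'                  nChromosomes = 1L, nCaseTrios = 20L, nControlTrios = 20L)
#' @export
simConfig <- function(seed = 1L, nChromosomes = 2L, chromLength = 3000000L,
                      nGenes = 540L, ncRnaFraction = 0.04,
                      nCaseTrios = 500L, nControlTrios = 500L,
                      dnmRate = 90, codingDnmsPerChild = 1.27,
                      enrichment = setNames(numeric(0), character(0)),
                      depthMean = 30, depthSize = 10,
                      inheritedHetsPerChild = 10, decoysPerType = 10L,
                      indelFraction = 0.08, caddTailFraction = 0.018,
                      gammaShape = 4, gammaScale = 0.25,
                      flankBp = 1000L, nBlacklistGenes = 2L,
                      maskWindowsPerChrom = 3L, maskWindowBp = 2000L) {
  new("SimConfig", seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
      ncRnaFraction = ncRnaFraction,
      nCaseTrios = as.integer(nCaseTrios),
      nControlTrios = as.integer(nControlTrios),
      dnmRate = dnmRate, codingDnmsPerChild = codingDnmsPerChild,
      enrichment = enrichment, depthMean = depthMean, depthSize = depthSize,
      inheritedHetsPerChild = inheritedHetsPerChild,
      decoysPerType = as.integer(decoysPerType),
      indelFraction = indelFraction, caddTailFraction = caddTailFraction,
      gammaShape = gammaShape, gammaScale = gammaScale,
      flankBp = as.integer(flankBp),
      nBlacklistGenes = as.integer(nBlacklistGenes),
      maskWindowsPerChrom = as.integer(maskWindowsPerChrom),
      maskWindowBp = as.integer(maskWindowBp))
}

#' Gene models with derived coding and noncoding lengths
#'
#' Transcript, exon and CDS intervals for a set of non-overlapping genes,
#' plus derived per-gene quantities used by the enrichment tests: the coding
#' length (sum of CDS widths) and, once scores are attached, the noncoding
#' functional length (count of noncoding footprint positions whose
#' deleteriousness score is >= 15).
#'
#' @slot genes GRanges of transcript spans; mcols: gene_id, is_coding,
#'   coding_length, pLI, and (after [noncodingFunctionalLength()] /
#'   [intergenicFunctionalLength()]) noncoding_functional_length and
#'   intergenic_functional_length.
#' @slot exons,cds GRangesList named by gene id (cds empty for ncRNA genes).
#' @slot flank integer flank (bp) defining the gene footprint
#'   (transcript span extended both sides, clipped to the chromosome).
#' @export
setClass("GeneModelSet", representation(
  genes = "GRanges", exons = "GRangesList", cds = "GRangesList",
  flank = "integer"))

setValidity("GeneModelSet", function(object) {
  msg <- character()
  ids <- object@genes$gene_id
  if (is.null(ids) || anyDuplicated(ids)) msg <- c(msg, "gene ids must be unique")
  if (!identical(names(object@exons), ids) || !identical(names(object@cds), ids))
    msg <- c(msg, "exons/cds must be named by gene id in gene order")
  if (!length(msg)) {
    for (i in seq_along(ids)) {
      ex <- IRanges::ranges(object@exons[[i]])
      cd <- IRanges::ranges(object@cds[[i]])
      tx <- IRanges::ranges(object@genes[i])
      if (length(ex) && (is.unsorted(BiocGenerics::start(ex)) ||
                         any(IRanges::width(IRanges::reduce(ex)) != IRanges::width(ex)) ||
                         length(IRanges::reduce(ex)) != length(ex)))
        msg <- c(msg, sprintf("exons of %s not sorted/disjoint", ids[i]))
      if (length(ex) && length(IRanges::setdiff(ex, tx)))
        msg <- c(msg, sprintf("exons of %s outside transcript", ids[i]))
      if (length(cd) && length(IRanges::setdiff(cd, ex)))
        msg <- c(msg, sprintf("CDS of %s outside exons", ids[i]))
      if (length(cd) && sum(IRanges::width(cd)) != object@genes$coding_length[i])
        msg <- c(msg, sprintf("coding_length of %s inconsistent", ids[i]))
      if (length(msg) > 4) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModelSet-class gene identifiers, in model order.
#' @param object,x a `GeneModelSet`.
#' @export
geneIds <- function(x) x@genes$gene_id

#' @describeIn GeneModelSet-class per-gene metadata as a data.frame
#'   (chrom, start, end, strand plus all derived columns).
#' @export
geneTable <- function(x) {
  g <- x@genes
  cbind(data.frame(chrom = as.character(GenomeInfoDb::seqnames(g)),
                   start = BiocGenerics::start(g), end = BiocGenerics::end(g),
                   strand = as.character(BiocGenerics::strand(g))),
        as.data.frame(S4Vectors::mcols(g)))
}

#' @describeIn GeneModelSet-class transcript spans extended by the flank and
#'   clipped to chromosome bounds (the "footprint" used for region
#'   classification and the noncoding length).
#' @export
footprints <- function(x) {
  fp <- x@genes + x@flank
  GenomicRanges::trim(fp)
}

#' @describeIn GeneModelSet-class exon intervals as a GRangesList by gene.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GeneModelSet-class CDS intervals as a GRangesList by gene.
#' @export
cdsRanges <- function(x) x@cds

setMethod("show", "GeneModelSet", function(object) {
  g <- object@genes
  cat(sprintf("GeneModelSet: %d genes (%d coding) on %d sequence(s), flank %d bp\n",
              length(g), sum(g$is_coding),
              length(GenomeInfoDb::seqlevels(g)), object@flank))
  cat(sprintf("  total coding length: %d bp\n", sum(g$coding_length)))
})

#' Simulated trio cohort with planted ground truth
#'
#' One row of `records` per variant per family (child + mother + father
#' genotype metrics); `truth` carries the planted origin of every record:
#' clean de novo mutation, filter-violating decoy (with the criterion it
#' violates), or inherited heterozygous background.
#'
#' @slot records data.frame of trio variant records (family_id, cohort,
#'   chrom, pos, ref, alt, child/mother/father GT, AD, DP, GQ fields).
#' @slot truth data.frame aligned row-wise with `records`: origin
#'   ("dnm", "decoy", "inherited"), decoy_type, true_gene, true_class.
#' @slot config the [SimConfig-class] that produced the cohort.
#' @export
setClass("TrioCohort", representation(
  records = "data.frame", truth = "data.frame", config = "SimConfig"))

setValidity("TrioCohort", function(object) {
  if (nrow(object@records) != nrow(object@truth))
    "records and truth must be row-aligned" else TRUE
})

setMethod("show", "TrioCohort", function(object) {
  tr <- object@truth
  cat(sprintf("TrioCohort: %d families (%d case, %d control), %d records\n",
              length(unique(object@records$family_id)),
              object@config@nCaseTrios, object@config@nControlTrios,
              nrow(object@records)))
  print(table(origin = tr$origin, cohort = object@records$cohort))
})

#' @describeIn TrioCohort-class the trio variant records.
#' @param x a `TrioCohort`.
#' @export
cohortRecords <- function(x) x@records

#' @describeIn TrioCohort-class the planted ground-truth annotations.
#' @export
cohortTruth <- function(x) x@truth

#' A complete synthetic study: genome, tracks and cohort
#'
#' Bundle of every artifact the pipeline consumes, generated deterministically
#' from one [SimConfig-class]: reference sequences, gene models,
#' per-gene mutation rates, per-site score track, 1 kb background bins,
#' low-mappability mask, population allele-frequency table, gene sets, and
#' the simulated trio cohort.
#'
#' @export
setClass("SyntheticStudy", representation(
  config = "SimConfig", reference = "DNAStringSet", genes = "GeneModelSet",
  rates = "data.frame", scores = "list", bins = "GRanges", mask = "GRanges",
  afTable = "data.frame", cohort = "TrioCohort", geneSets = "list"))

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy (seed %d): %d bp genome, %d genes, %d bins\n",
              object@config@seed, sum(Biostrings::width(object@reference)),
              length(object@genes@genes), length(object@bins)))
  show(object@cohort)
})
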