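# Trio cohort simulation: per-child Poisson DNM counts, per-gene placement
# proportional to mutation rate (times case-only enrichment multipliers),
# Mendelian genotypes with fabricated AD/DP/GQ, filter-violating decoys and
# inherited heterozygous background variants.

# Uniform position sampling over a (reduced) GRanges pool.
.samplePool <- function(pool, n) {
  if (n == 0L) return(data.frame(chrom = character(0), pos = integer(0)))
  w <- IRanges::width(pool)
  total <- sum(w)
  if (total == 0L) stop("empty sampling pool", call. = FALSE)
  off <- sample.int(total, n, replace = TRUE)
  cw <- cumsum(w)
  idx <- findInterval(off - 1L, c(0L, cw), rightmost.closed = FALSE)
  # findInterval over [0, cw): off-1 in [cw[i-1], cw[i]) -> interval i
  pos <- BiocGenerics::start(pool)[idx] + (off - c(0L, cw)[idx]) - 1L
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(pool))[idx], pos = pos)
}

# Reference base(s) at given positions; len gives span width.
.refSeqAt <- function(reference, chrom, pos, len = 1L) {
  out <- character(length(pos))
  len <- rep_len(len, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    at <- IRanges::IRanges(pos[sel], width = len[sel])
    out[sel] <- as.character(Biostrings::extractAt(reference[[ch]], at))
  }
  out
}

# Draw ref/alt alleles at sampled positions (SNVs and short indels).
.drawAlleles <- function(reference, chrom, pos, indelFraction) {
  n <- length(pos)
  isIndel <- runif(n) < indelFraction
  ref <- .refSeqAt(reference, chrom, pos)
  alt <- ref
  bases <- c("A", "C", "G", "T")
  # each base's three alternatives, indexed by base then 1:3
  altsOf <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  snv <- which(!isIndel)
  if (length(snv)) {
    pick <- sample.int(3L, length(snv), replace = TRUE)
    alt[snv] <- altsOf[cbind(match(ref[snv], bases), pick)]
  }
  idl <- which(isIndel)
  if (length(idl)) {
    dlen <- sample(1:3, length(idl), replace = TRUE)
    chromLen <- setNames(Biostrings::width(reference), names(reference))
    isDel <- runif(length(idl)) < 0.5 &
      pos[idl] + dlen <= chromLen[chrom[idl]]
    del <- idl[isDel]
    if (length(del)) {
      ref[del] <- .refSeqAt(reference, chrom[del], pos[del], dlen[isDel] + 1L)
      alt[del] <- substr(ref[del], 1L, 1L)
    }
    ins <- idl[!isDel]
    if (length(ins)) {
      dl <- dlen[!isDel]
      extra <- vapply(split(sample(bases, sum(dl), replace = TRUE),
                            rep(seq_along(ins), dl)),
                      paste, character(1), collapse = "")
      alt[ins] <- paste0(ref[ins], extra)
    }
  }
  list(ref = ref, alt = alt)
}

# Clean genotype metrics guaranteed to satisfy every DNM filter.
.cleanMetrics <- function(n, config) {
  dp <- as.integer(pmax(rnbinom(n, mu = config@depthMean,
                                size = config@depthSize), 14L))
  adAlt <- rbinom(n, dp, 0.5)
  adAlt <- as.integer(pmin(pmax(adAlt, pmax(6L, ceiling(0.25 * dp))),
                           floor(0.75 * dp)))
  data.frame(child_gt = "0/1", mother_gt = "0/0", father_gt = "0/0",
             child_ad_ref = dp - adAlt, child_ad_alt = adAlt, child_dp = dp,
             mother_dp = as.integer(pmax(rnbinom(n, mu = config@depthMean,
                                                 size = config@depthSize), 10L)),
             father_dp = as.integer(pmax(rnbinom(n, mu = config@depthMean,
                                                 size = config@depthSize), 10L)),
             child_gq = sample(40:99, n, replace = TRUE),
             mother_gq = sample(40:99, n, replace = TRUE),
             father_gq = sample(40:99, n, replace = TRUE))
}

#' Generate a low-mappability mask
#'
#' Carves a configurable number of fixed-width windows per chromosome out of
#' the intergenic space (outside all gene footprints). Clean DNMs are never
#' planted inside the mask; mappability decoys always are.
#'
#' @param reference DNAStringSet.
#' @param geneModels a [GeneModelSet-class].
#' @param config a [SimConfig-class].
#' @return GRanges mask (possibly empty).
#' @export
generateMappabilityMask <- function(reference, geneModels, config) {
  si <- .refSeqinfo(reference)
  inter <- GenomicRanges::gaps(GenomicRanges::reduce(footprints(geneModels),
                                                     ignore.strand = TRUE))
  inter <- inter[BiocGenerics::strand(inter) == "*"]
  .withStageSeed(config@seed, "mask", {
    out <- list()
    for (ch in names(reference)) {
      cand <- inter[GenomeInfoDb::seqnames(inter) == ch &
                    IRanges::width(inter) >= config@maskWindowBp + 200L]
      if (!length(cand)) next
      k <- min(config@maskWindowsPerChrom, length(cand))
      pick <- sample(seq_along(cand), k)
      for (i in pick) {
        s <- BiocGenerics::start(cand)[i] +
          sample.int(IRanges::width(cand)[i] - config@maskWindowBp, 1L)
        out[[length(out) + 1L]] <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(s, width = config@maskWindowBp), seqinfo = si)
      }
    }
    if (!length(out)) GenomicRanges::GRanges(seqinfo = si)
    else GenomicRanges::reduce(do.call(c, out))
  })
}

#' Simulate a trio cohort with planted DNMs, decoys and inherited variants
#'
#' Per child the DNM count is Poisson(`dnmRate`). Each DNM lands in the
#' coding sequence of gene g with probability 2*p_g*m_g / dnmRate (m_g the
#' case-only enrichment multiplier, 1 for controls), so per-gene coding
#' counts are exactly Poisson(2 * p_g * m_g * n_trios); the remaining mass
#' is spread uniformly over the noncoding genome (enriched genes' noncoding
#' footprints upweighted by m_g). Children are heterozygous with clean
#' AD/DP/GQ at DNM sites and both parents are homozygous reference.
#' Filter-violating decoys (one per stated filter criterion, plus
#' parent-carrier and child-hom-alt detection decoys) and inherited
#' heterozygous background variants are added per the config.
#'
#' @param config a [SimConfig-class].
#' @param reference DNAStringSet.
#' @param geneModels a [GeneModelSet-class].
#' @param rates data.frame from [generateMutationRates()].
#' @param mask optional GRanges low-mappability mask (excluded from clean
#'   placement; mappability decoys are placed inside it).
#' @return A [TrioCohort-class]; `cohortTruth()` rows align with
#'   `cohortRecords()` rows.
#' @export
simulateTrioCohort <- function(config, reference, geneModels, rates,
                               mask = NULL) {
  stopifnot(is(config, "SimConfig"))
  g <- geneModels@genes
  ids <- g$gene_id
  if (length(config@enrichment)) {
    unknown <- setdiff(names(config@enrichment), ids)
    if (length(unknown))
      stop("enrichment names unknown gene ids: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  si <- .refSeqinfo(reference)
  if (is.null(mask)) mask <- GenomicRanges::GRanges(seqinfo = si)

  rateIdx <- match(rates$gene_id, ids)
  blFp <- footprints(geneModels)[grepl("^(HLA|MUC)", ids)]
  chromOfGene <- as.character(GenomeInfoDb::seqnames(g))
  # a gene's coding mutational target = CDS plus canonical splice windows,
  # matching the coding test's "exonic + splicing" observed definition
  cdsPools <- lapply(rateIdx, function(i) {
    sp <- .spliceRanges(geneModels@exons[[i]], g[i])
    ir <- IRanges::reduce(c(IRanges::ranges(geneModels@cds[[i]]), sp))
    GenomicRanges::GRanges(rep(chromOfGene[i], length(ir)), ir, seqinfo = si)
  })
  allCds <- GenomicRanges::reduce(
    c(unlist(geneModels@cds, use.names = FALSE),
      do.call(c, unname(cdsPools))), ignore.strand = TRUE)
  genome <- GenomicRanges::GRanges(names(reference),
                                   IRanges::IRanges(1L, Biostrings::width(reference)),
                                   seqinfo = si)
  noncod <- GenomicRanges::setdiff(genome, allCds, ignore.strand = TRUE)
  cleanNc <- GenomicRanges::setdiff(noncod,
              GenomicRanges::reduce(c(GenomicRanges::granges(blFp),
                                      GenomicRanges::granges(mask)),
                                    ignore.strand = TRUE),
              ignore.strand = TRUE)

  # enrichment applies to a gene's coding rate and its noncoding footprint
  mult <- setNames(rep(1, length(ids)), ids)
  mult[names(config@enrichment)] <- config@enrichment
  enrichedNc <- names(config@enrichment)[config@enrichment != 1]
  encPools <- lapply(enrichedNc, function(gid) {
    fp <- footprints(geneModels)[match(gid, ids)]
    GenomicRanges::setdiff(GenomicRanges::granges(fp), allCds,
                           ignore.strand = TRUE)
  })
  names(encPools) <- enrichedNc
  basePool <- cleanNc
  if (length(encPools))
    basePool <- GenomicRanges::setdiff(basePool,
      GenomicRanges::reduce(do.call(c, unname(encPools)), ignore.strand = TRUE),
      ignore.strand = TRUE)

  simArm <- function(cohort, n, famPrefix, enriched) {
    m <- if (enriched) mult[rates$gene_id] else rep(1, nrow(rates))
    pCoding <- 2 * rates$p_total * m / config@dnmRate
    if (sum(pCoding) >= 1)
      stop("coding placement mass exceeds dnmRate", call. = FALSE)
    encMult <- if (enriched) mult[names(encPools)] else rep(1, length(encPools))
    ncW <- c(if (length(encPools))
               vapply(seq_along(encPools), function(i)
                 sum(IRanges::width(encPools[[i]])) * encMult[i], numeric(1))
             else numeric(0),
             sum(IRanges::width(basePool)))
    probs <- c(pCoding, (1 - sum(pCoding)) * ncW / sum(ncW))
    nCat <- length(probs)
    counts <- rpois(n, config@dnmRate)
    total <- sum(counts)
    fam <- rep(sprintf("%s%04d", famPrefix, seq_len(n)), counts)
    cat <- sample.int(nCat, total, replace = TRUE, prob = probs)
    chrom <- character(total); pos <- integer(total)
    trueGene <- rep(NA_character_, total)
    trueClass <- rep("noncoding", total)
    for (k in seq_len(nrow(rates))) {
      sel <- which(cat == k)
      if (!length(sel)) next
      sp <- .samplePool(cdsPools[[k]], length(sel))
      chrom[sel] <- sp$chrom; pos[sel] <- sp$pos
      trueGene[sel] <- rates$gene_id[k]; trueClass[sel] <- "coding"
    }
    for (j in seq_along(encPools)) {
      sel <- which(cat == nrow(rates) + j)
      if (!length(sel)) next
      sp <- .samplePool(encPools[[j]], length(sel))
      chrom[sel] <- sp$chrom; pos[sel] <- sp$pos
      trueGene[sel] <- names(encPools)[j]
    }
    sel <- which(cat == nCat)
    if (length(sel)) {
      sp <- .samplePool(basePool, length(sel))
      chrom[sel] <- sp$chrom; pos[sel] <- sp$pos
    }
    al <- .drawAlleles(reference, chrom, pos, config@indelFraction)
    met <- .cleanMetrics(total, config)
    rec <- cbind(data.frame(family_id = fam, cohort = cohort,
                            chrom = chrom, pos = pos,
                            ref = al$ref, alt = al$alt), met)
    tru <- data.frame(origin = rep("dnm", total), decoy_type = NA_character_,
                      true_gene = trueGene, true_class = trueClass,
                      af = NA_real_)
    list(rec = rec, tru = tru)
  }

  mkDecoys <- function(cohort, n, famPrefix) {
    types <- c("ad_alt", "child_gq", "parent_gq", "parent_dp", "pop_af",
               "allele_balance", "parent_het", "child_hom_alt")
    if (length(mask)) types <- c(types, "mappability")
    if (length(blFp)) types <- c(types, "blacklist")
    k <- config@decoysPerType
    if (k == 0L) return(NULL)
    out <- lapply(types, function(ty) {
      pool <- switch(ty, mappability = GenomicRanges::granges(mask),
                     blacklist = GenomicRanges::reduce(
                       GenomicRanges::granges(blFp), ignore.strand = TRUE),
                     basePool)
      sp <- .samplePool(pool, k)
      refb <- .refSeqAt(reference, sp$chrom, sp$pos)
      alt <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      met <- .cleanMetrics(k, config)
      af <- rep(NA_real_, k)
      switch(ty,
        ad_alt = { met$child_dp <- 16L; met$child_ad_alt <- 5L
                   met$child_ad_ref <- 11L },
        child_gq = met$child_gq <- 10L,
        parent_gq = met$mother_gq <- 10L,
        parent_dp = met$father_dp <- 8L,
        pop_af = af <- round(runif(k, 0.001, 0.05), 4),
        allele_balance = { met$child_dp <- 40L; met$child_ad_alt <- 6L
                           met$child_ad_ref <- 34L },
        parent_het = met$father_gt <- "0/1",
        child_hom_alt = met$child_gt <- "1/1",
        NULL)
      rec <- cbind(data.frame(
        family_id = sprintf("%s%04d", famPrefix, sample.int(n, k, replace = TRUE)),
        cohort = cohort, chrom = sp$chrom, pos = sp$pos,
        ref = unname(refb), alt = unname(alt)), met)
      tru <- data.frame(origin = rep("decoy", k), decoy_type = ty,
                        true_gene = NA_character_, true_class = "decoy",
                        af = af)
      list(rec = rec, tru = tru)
    })
    list(rec = do.call(rbind, lapply(out, `[[`, "rec")),
         tru = do.call(rbind, lapply(out, `[[`, "tru")))
  }

  mkInherited <- function(cohort, n, famPrefix) {
    counts <- rpois(n, config@inheritedHetsPerChild)
    total <- sum(counts)
    if (total == 0L) return(NULL)
    fam <- rep(sprintf("%s%04d", famPrefix, seq_len(n)), counts)
    sp <- .samplePool(basePool, total)
    al <- .drawAlleles(reference, sp$chrom, sp$pos, config@indelFraction)
    met <- .cleanMetrics(total, config)
    fromMother <- runif(total) < 0.5
    met$mother_gt[fromMother] <- "0/1"
    met$father_gt[!fromMother] <- "0/1"
    rec <- cbind(data.frame(family_id = fam, cohort = cohort,
                            chrom = sp$chrom, pos = sp$pos,
                            ref = al$ref, alt = al$alt), met)
    tru <- data.frame(origin = rep("inherited", total),
                      decoy_type = NA_character_,
                      true_gene = NA_character_, true_class = "inherited",
                      af = NA_real_)
    list(rec = rec, tru = tru)
  }

  .withStageSeed(config@seed, "cohort", {
    parts <- list(simArm("case", config@nCaseTrios, "CASE", TRUE),
                  simArm("control", config@nControlTrios, "CTRL", FALSE),
                  mkDecoys("case", config@nCaseTrios, "CASE"),
                  mkDecoys("control", config@nControlTrios, "CTRL"),
                  mkInherited("case", config@nCaseTrios, "CASE"),
                  mkInherited("control", config@nControlTrios, "CTRL"))
    parts <- parts[!vapply(parts, is.null, logical(1))]
    rec <- do.call(rbind, lapply(parts, `[[`, "rec"))
    tru <- do.call(rbind, lapply(parts, `[[`, "tru"))
    # clean DNMs colliding with a population-AF decoy site would fail the
    # AF filter through no fault of their own; drop them
    afKey <- paste(rec$chrom, rec$pos)[tru$origin == "decoy" &
                                       tru$decoy_type == "pop_af"]
    drop <- tru$origin != "decoy" & paste(rec$chrom, rec$pos) %in% afKey
    rec <- rec[!drop, , drop = FALSE]; tru <- tru[!drop, , drop = FALSE]
    rec$record_id <- seq_len(nrow(rec))
    rownames(rec) <- rownames(tru) <- NULL
    new("TrioCohort", records = rec, truth = tru, config = config)
  })
}

#' Population allele-frequency table implied by the planted decoys
#'
#' @param cohort a [TrioCohort-class].
#' @return data.frame (chrom, pos, ref, alt, af) for every pop_af decoy site.
#' @export
cohortAfTable <- function(cohort) {
  sel <- cohort@truth$origin == "decoy" &
    cohort@truth$decoy_type %in% "pop_af"
  r <- cohort@records[sel, c("chrom", "pos", "ref", "alt")]
  r$af <- cohort@truth$af[sel]
  unique(r[order(r$chrom, r$pos), ])
}

#' Per-gene planted DNM counts by cohort
#'
#' @param cohort a [TrioCohort-class].
#' @return data.frame gene_id x cohort counts of planted (clean) DNMs.
#' @export
plantedCounts <- function(cohort) {
  sel <- cohort@truth$origin == "dnm" & !is.na(cohort@truth$true_gene)
  as.data.frame(table(gene_id = cohort@truth$true_gene[sel],
                      cohort = cohort@records$cohort[sel],
                      class = cohort@truth$true_class[sel]),
                responseName = "planted")
}

#' Write one VCF 4.2 per family
#'
#' Samples are `<family>.p1` (child), `<family>.mo`, `<family>.fa`, FORMAT
#' `GT:AD:DP:GQ` with AD as "ref,alt". Output is byte-deterministic for a
#' given cohort.
#'
#' @param cohort a [TrioCohort-class].
#' @param dir output directory (created if needed).
#' @param reference DNAStringSet (for contig header lines).
#' @return character vector of file paths, invisibly.
#' @export
writeCohortVcfs <- function(cohort, dir, reference) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- cohort@records
  hdrTop <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(reference),
                      Biostrings::width(reference)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  paths <- character(0)
  for (fam in sort(unique(rec$family_id))) {
    fr <- rec[rec$family_id == fam, ]
    fr <- fr[order(match(fr$chrom, names(reference)), fr$pos, fr$ref, fr$alt), ]
    halfAd <- function(gt, dp) ifelse(gt == "0/1",
      paste0(dp - pmax(1L, dp %/% 2L), ",", pmax(1L, dp %/% 2L)),
      paste0(dp, ",0"))
    childFmt <- sprintf("%s:%d,%d:%d:%d", fr$child_gt, fr$child_ad_ref,
                        fr$child_ad_alt, fr$child_dp, fr$child_gq)
    childFmt[fr$child_gt == "1/1"] <- sprintf("1/1:%d,%d:%d:%d",
      fr$child_ad_ref[fr$child_gt == "1/1"],
      fr$child_ad_alt[fr$child_gt == "1/1"],
      fr$child_dp[fr$child_gt == "1/1"], fr$child_gq[fr$child_gt == "1/1"])
    moFmt <- sprintf("%s:%s:%d:%d", fr$mother_gt,
                     halfAd(fr$mother_gt, fr$mother_dp), fr$mother_dp, fr$mother_gq)
    faFmt <- sprintf("%s:%s:%d:%d", fr$father_gt,
                     halfAd(fr$father_gt, fr$father_dp), fr$father_dp, fr$father_gq)
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t.\tGT:AD:DP:GQ\t%s\t%s\t%s",
                     fr$chrom, fr$pos, fr$ref, fr$alt, childFmt, moFmt, faFmt)
    path <- file.path(dir, paste0(fam, ".vcf"))
    writeLines(c(hdrTop,
                 sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s.p1\t%s.mo\t%s.fa",
                         fam, fam, fam),
                 lines), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write the planted truth set
#' @param cohort a [TrioCohort-class].
#' @param path output file.
#' @export
writeTruthSet <- function(cohort, path) {
  writeTsv(cbind(cohort@records[, c("record_id", "family_id", "cohort",
                                    "chrom", "pos", "ref", "alt")],
                 cohort@truth), path, "truth_set")
}

#' Write a BED mask (0-based half-open)
#' @param mask GRanges.
#' @param path output file.
#' @export
writeMaskBed <- function(mask, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(mask)),
                   start = BiocGenerics::start(mask) - 1L,
                   end = BiocGenerics::end(mask))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate gene sets for burden analysis
#'
#' Three sets mirroring the usual burden-test groupings: LoF-constrained
#' genes (pLI > 0.9), a "known risk gene" set (a seeded random subset of
#' constrained genes plus others), and all rate-table genes.
#'
#' @param geneModels a [GeneModelSet-class].
#' @param config a [SimConfig-class].
#' @return named list of character vectors of gene ids.
#' @export
generateGeneSets <- function(geneModels, config) {
  g <- geneModels@genes
  .withStageSeed(config@seed, "genesets", {
    constrained <- g$gene_id[!is.na(g$pLI) & g$pLI > 0.9]
    known <- sort(sample(g$gene_id, max(5L, length(g) %/% 10L)))
    list(all_genes = g$gene_id, constrained = constrained, known_risk = known)
  })
}

#' Generate every artifact of a synthetic study
#'
#' Runs all generator stages in order (reference, gene models with start and
#' stop codons imprinted, mutation rates, site scores, background bins,
#' mappability mask, gene sets, trio cohort) and optionally serializes the
#' whole study to a directory (FASTA, per-family VCFs, tab-separated tables,
#' BED mask, YAML manifest).
#'
#' @param config a [SimConfig-class].
#' @param dir optional output directory.
#' @param scores generate the per-site score track (set FALSE to skip when
#'   only coding analyses are needed).
#' @return A [SyntheticStudy-class].
#' @export
simulateStudy <- function(config, dir = NULL, scores = TRUE) {
  ref <- generateReference(config)
  gm <- generateGeneModels(config, ref)
  ref <- imprintGeneSignals(ref, gm)
  rates <- generateMutationRates(gm, config)
  sc <- if (scores) generateSiteScores(ref, gm, config) else list()
  bins <- generateGnocchiBins(ref, gm, config)
  mask <- generateMappabilityMask(ref, gm, config)
  sets <- generateGeneSets(gm, config)
  cohort <- simulateTrioCohort(config, ref, gm, rates, mask = mask)
  study <- new("SyntheticStudy", config = config, reference = ref,
               genes = gm, rates = rates, scores = sc, bins = bins,
               mask = mask, afTable = cohortAfTable(cohort),
               cohort = cohort, geneSets = sets)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeReferenceFasta(ref, file.path(dir, "reference.fa"))
    writeGeneModels(gm, file.path(dir, "genes.tsv"))
    writeRateTable(rates, file.path(dir, "rates.tsv"))
    writeBinTable(bins, file.path(dir, "bins.tsv"))
    writeMaskBed(mask, file.path(dir, "mask.bed"))
    writeTsv(study@afTable, file.path(dir, "af.tsv"), "allele_frequencies")
    writeTruthSet(cohort, file.path(dir, "truth.tsv"))
    for (nm in names(sets))
      writeLines(sets[[nm]], file.path(dir, paste0("geneset_", nm, ".txt")))
    writeCohortVcfs(cohort, file.path(dir, "vcf"), ref)
    yaml::write_yaml(list(seed = config@seed,
                          n_case_trios = config@nCaseTrios,
                          n_control_trios = config@nControlTrios,
                          genome_bp = sum(Biostrings::width(ref)),
                          n_genes = config@nGenes),
                     file.path(dir, "manifest.yaml"))
  }
  study
}
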