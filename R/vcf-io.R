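# Reading per-family trio VCFs into the flat record table the caller uses.

#' Read a per-family trio VCF
#'
#' Parses a VCF 4.2 with child + mother + father samples and FORMAT
#' `GT:AD:DP:GQ` via `VariantAnnotation::readVcf`, returning one row per
#' alternate allele with the child's per-allele depths. Sample roles are
#' inferred from the `.p1` / `.mo` / `.fa` suffix convention when present,
#' else taken positionally (child, mother, father).
#'
#' @param path VCF file.
#' @param familyId family label for the records (default: file name stem).
#' @param cohort cohort label ("case"/"control"), attached verbatim.
#' @return data.frame of trio variant records.
#' @export
readTrioVcf <- function(path, familyId = NULL,
                        cohort = NA_character_) {
  if (is.null(familyId))
    familyId <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- tryCatch(VariantAnnotation::readVcf(path),
                  error = function(e) stop("failed to parse VCF '", basename(path),
                                           "': ", conditionMessage(e), call. = FALSE))
  smp <- colnames(vcf)
  if (length(smp) < 3L)
    stop("trio VCF must contain three samples, found ", length(smp), call. = FALSE)
  role <- function(suffix, fallback) {
    hit <- grep(paste0("\\.", suffix, "$"), smp)
    if (length(hit) == 1L) hit else fallback
  }
  ci <- role("p1", 1L); mi <- role("mo", 2L); fi <- role("fa", 3L)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  gq <- VariantAnnotation::geno(vcf)$GQ
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altL)
  row <- rep(seq_len(nrow(vcf)), nAlt)
  altIdx <- unlist(lapply(nAlt, seq_len), use.names = FALSE)
  adAt <- function(i, j, k) {       # sample j, variant rows i, allele slot k
    v <- ad[cbind(i, j)]
    vapply(seq_along(v), function(t) {
      x <- v[[t]]
      if (length(x) >= k[t]) as.integer(x[k[t]]) else NA_integer_
    }, integer(1))
  }
  data.frame(
    family_id = familyId, cohort = cohort,
    chrom = as.character(GenomeInfoDb::seqnames(rr))[row],
    pos = BiocGenerics::start(rr)[row],
    ref = as.character(VariantAnnotation::ref(vcf))[row],
    alt = as.character(unlist(altL, use.names = FALSE)),
    child_gt = unname(gt[cbind(row, ci)]),
    mother_gt = unname(gt[cbind(row, mi)]),
    father_gt = unname(gt[cbind(row, fi)]),
    child_ad_ref = adAt(row, ci, rep(1L, length(row))),
    child_ad_alt = adAt(row, ci, altIdx + 1L),
    child_dp = as.integer(dp[cbind(row, ci)]),
    mother_dp = as.integer(dp[cbind(row, mi)]),
    father_dp = as.integer(dp[cbind(row, fi)]),
    child_gq = as.integer(gq[cbind(row, ci)]),
    mother_gq = as.integer(gq[cbind(row, mi)]),
    father_gq = as.integer(gq[cbind(row, fi)]),
    stringsAsFactors = FALSE)
}

# Left-align one biallelic ref/alt pair against the reference (vt-style):
# trim shared rightmost bases (extending left when an allele would empty),
# then trim shared leftmost bases keeping a one-base anchor.
.leftAlignOne <- function(chromSeq, pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  repeat {
    if (length(r) && length(a) && r[length(r)] == a[length(a)] &&
        !(length(r) == 1L && length(a) == 1L)) {
      last <- r[length(r)]
      r <- r[-length(r)]; a <- a[-length(a)]
      if (!length(r) || !length(a)) {
        if (pos == 1L) {            # cannot extend past the chromosome start
          r <- c(r, last); a <- c(a, last); break
        }
        pos <- pos - 1L
        b <- as.character(Biostrings::subseq(chromSeq, pos, pos))
        r <- c(b, r); a <- c(b, a)
      }
    } else break
  }
  while (length(r) >= 2L && length(a) >= 2L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Normalize and split variant records
#'
#' Splits multi-allelic rows (comma-separated `alt`) into one biallelic
#' record per alternate allele, drops spanning-deletion (`*`) and symbolic
#' (`<...>`) alleles with a logged count, and left-aligns indels against the
#' reference. Input order is preserved.
#'
#' @param records data.frame of trio variant records.
#' @param reference DNAStringSet.
#' @return data.frame of normalized biallelic records.
#' @export
normalizeVariants <- function(records, reference) {
  multi <- grepl(",", records$alt)
  if (any(multi)) {
    pieces <- strsplit(records$alt, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(records)), lengths(pieces))
    records <- records[idx, , drop = FALSE]
    records$alt <- unlist(pieces, use.names = FALSE)
  }
  bad <- records$alt == "*" | grepl("^<", records$alt)
  if (any(bad)) {
    message("normalizeVariants: dropped ", sum(bad),
            " spanning/symbolic alt allele(s)")
    records <- records[!bad, , drop = FALSE]
  }
  needs <- which(nchar(records$ref) != nchar(records$alt) |
                 nchar(records$ref) > 1L)
  for (i in needs) {
    la <- .leftAlignOne(reference[[records$chrom[i]]], records$pos[i],
                        records$ref[i], records$alt[i])
    records$pos[i] <- la$pos
    records$ref[i] <- la$ref
    records$alt[i] <- la$alt
  }
  rownames(records) <- NULL
  records
}
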