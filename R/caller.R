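# De novo mutation candidate detection and the eight-criterion filter chain.

#' Detect candidate de novo mutations in trio records
#'
#' A candidate DNM is a variant where the child carries the alternate allele
#' heterozygously and both parents are homozygous reference. All other
#' records are excluded with a reason code: `parent_missing` (ungenotyped
#' parent), `parent_carrier` (allele present in a parent),
#' `child_hom_alt` (implausible de novo genotype), `child_no_alt`.
#'
#' @param records data.frame of normalized biallelic trio records.
#' @return the input with logical `candidate` and character
#'   `exclude_reason` columns appended.
#' @export
detectCandidateDnms <- function(records) {
  norm <- function(gt) gsub("|", "/", gt, fixed = TRUE)
  cg <- norm(records$child_gt)
  mg <- norm(records$mother_gt)
  fg <- norm(records$father_gt)
  missing <- function(gt) is.na(gt) | gt %in% c("./.", ".", ".|.")
  het <- cg %in% c("0/1", "1/0")
  homAlt <- cg %in% "1/1"
  parentMissing <- missing(mg) | missing(fg)
  parentCarrier <- !parentMissing &
    (grepl("1", mg, fixed = TRUE) | grepl("1", fg, fixed = TRUE))
  reason <- rep(NA_character_, nrow(records))
  reason[!het & !homAlt] <- "child_no_alt"
  reason[homAlt] <- "child_hom_alt"
  reason[het & parentMissing] <- "parent_missing"
  reason[het & !parentMissing & parentCarrier] <- "parent_carrier"
  records$candidate <- het & !parentMissing & !parentCarrier
  records$exclude_reason <- reason
  records
}

#' Allele balance of the child genotype
#'
#' Fraction of the child's reads supporting the alternate allele
#' (AB.ALT = AD_alt / (AD_ref + AD_alt)). Zero total depth gives NA (the
#' record then fails filtering with reason `ab_undefined`).
#'
#' @param adRef,adAlt child reference/alternate allelic depths.
#' @return numeric vector in \[0, 1\] (NA where depth is zero).
#' @examples
#' alleleBalance(10, 10)  # 0.5
#' alleleBalance(30, 10)  # 0.25
#' @export
alleleBalance <- function(adRef, adAlt) {
  tot <- adRef + adAlt
  ifelse(is.na(tot) | tot <= 0, NA_real_, adAlt / tot)
}

#' Filtering thresholds for DNM calling
#'
#' Defaults encode the standard trio filter chain: child alternate allelic
#' depth >= 6, child GQ >= 25, both parents GQ >= 20 and DP strictly > 8,
#' population allele frequency < 0.1% (missing treated as novel), allele
#' balance within \[0.25, 0.75\] inclusive, low-mappability mask exclusion,
#' difficult-region gene blacklist by symbol prefix (HLA, MUC), and a
#' 100 bp same-gene collapse window.
#'
#' @param minChildAdAlt,minChildGq,minParentGq,minParentDpExclusive,
#'   maxPopAf,abLow,abHigh,collapseWindowBp,blacklistPrefixes thresholds.
#' @return a validated named list of thresholds.
#' @export
dnmFilterThresholds <- function(minChildAdAlt = 6L, minChildGq = 25L,
                                minParentGq = 20L, minParentDpExclusive = 8L,
                                maxPopAf = 0.001, abLow = 0.25, abHigh = 0.75,
                                collapseWindowBp = 100L,
                                blacklistPrefixes = c("HLA", "MUC")) {
  th <- list(minChildAdAlt = minChildAdAlt, minChildGq = minChildGq,
             minParentGq = minParentGq,
             minParentDpExclusive = minParentDpExclusive,
             maxPopAf = maxPopAf, abLow = abLow, abHigh = abHigh,
             collapseWindowBp = collapseWindowBp,
             blacklistPrefixes = blacklistPrefixes)
  nums <- unlist(th[1:8])
  if (any(nums < 0)) stop("thresholds must be non-negative", call. = FALSE)
  if (!(abLow < abHigh && abHigh <= 1)) stop("need 0 <= abLow < abHigh <= 1",
                                             call. = FALSE)
  th
}

#' Apply the DNM filter chain to candidate calls
#'
#' Labels every candidate pass or fail, accumulating ALL violated criteria
#' (not first-hit) as reason codes: `ad_alt`, `child_gq`, `parent_gq`,
#' `parent_dp`, `pop_af`, `mappability`, `allele_balance` (or
#' `ab_undefined`), `blacklist`. Passing requires child AD_alt >= 6, child
#' GQ >= 25, both parents' GQ >= 20 and DP > 8 (strict), population AF
#' absent or < 0.001, position outside the mask, allele balance in
#' \[0.25, 0.75\], and the annotated gene not matching a blacklist prefix.
#'
#' @param candidates data.frame of candidate calls (optionally with a
#'   `gene_id` column for the blacklist criterion).
#' @param thresholds from [dnmFilterThresholds()].
#' @param mask GRanges of low-mappability regions (or NULL).
#' @param afTable data.frame (chrom, pos, ref, alt, af) or NULL.
#' @return the input with `pop_af`, `ab`, `filter_status` and
#'   `fail_reasons` (semicolon-joined) columns appended.
#' @export
applyDnmFilters <- function(candidates, thresholds = dnmFilterThresholds(),
                            mask = NULL, afTable = NULL) {
  n <- nrow(candidates)
  af <- rep(NA_real_, n)
  if (!is.null(afTable) && nrow(afTable)) {
    key <- paste(candidates$chrom, candidates$pos, candidates$ref, candidates$alt)
    hit <- match(key, paste(afTable$chrom, afTable$pos, afTable$ref, afTable$alt))
    af[!is.na(hit)] <- afTable$af[hit[!is.na(hit)]]
  }
  ab <- alleleBalance(candidates$child_ad_ref, candidates$child_ad_alt)
  inMask <- rep(FALSE, n)
  if (!is.null(mask) && length(mask)) {
    if (any(BiocGenerics::end(mask) <= BiocGenerics::start(mask) - 1L))
      stop("malformed mask interval (end <= start)", call. = FALSE)
    pts <- GenomicRanges::GRanges(candidates$chrom,
                                  IRanges::IRanges(candidates$pos, width = 1L))
    inMask <- IRanges::overlapsAny(pts, mask, ignore.strand = TRUE)
  }
  gene <- if ("gene_id" %in% names(candidates)) candidates$gene_id
          else rep(NA_character_, n)
  blacklisted <- !is.na(gene) & Reduce(`|`, lapply(thresholds$blacklistPrefixes,
    function(p) startsWith(gene, p)), rep(FALSE, n))
  fails <- list(
    ad_alt = candidates$child_ad_alt < thresholds$minChildAdAlt,
    child_gq = candidates$child_gq < thresholds$minChildGq,
    parent_gq = candidates$mother_gq < thresholds$minParentGq |
                candidates$father_gq < thresholds$minParentGq,
    parent_dp = candidates$mother_dp <= thresholds$minParentDpExclusive |
                candidates$father_dp <= thresholds$minParentDpExclusive,
    pop_af = !is.na(af) & af >= thresholds$maxPopAf,
    mappability = inMask,
    allele_balance = !is.na(ab) & (ab < thresholds$abLow | ab > thresholds$abHigh),
    ab_undefined = is.na(ab),
    blacklist = blacklisted)
  fails <- lapply(fails, function(x) { x[is.na(x)] <- TRUE; x })
  reasons <- rep("", n)
  for (nm in names(fails))
    reasons <- ifelse(fails[[nm]],
                      ifelse(reasons == "", nm, paste0(reasons, ";", nm)),
                      reasons)
  candidates$pop_af <- af
  candidates$ab <- ab
  candidates$fail_reasons <- reasons
  candidates$filter_status <- ifelse(reasons == "", "pass", "fail")
  candidates
}

# Consequence/region severity used for the 100 bp same-gene collapse;
# larger is more severe.
.SEVERITY <- c(frameshift_deletion = 10, frameshift_insertion = 10,
               startloss = 10, stopgain = 10, stoploss = 10, splicing = 10,
               missense = 9, synonymous = 8, nonframeshift_indel = 8,
               other = 8, ncRNA_splicing = 7, UTR5 = 6, UTR3 = 6,
               intronic = 5, upstream = 4, downstream = 4,
               ncRNA_exonic = 3, ncRNA_intronic = 3, intergenic = 1)

#' Severity rank of a call for the collapse rule
#'
#' LGD consequences (frameshift, stopgain, startloss, stoploss, canonical
#' splicing) outrank missense, which outranks other exonic classes, then
#' noncoding splicing, UTRs, intronic, flanking, ncRNA, intergenic.
#'
#' @param consequence consequence class (NA for noncoding calls).
#' @param regionClass region class.
#' @return numeric severity rank (larger = more severe).
#' @export
severityRank <- function(consequence, regionClass) {
  key <- ifelse(!is.na(consequence) & consequence %in% names(.SEVERITY),
                consequence, regionClass)
  unname(ifelse(key %in% names(.SEVERITY), .SEVERITY[key], 0))
}

#' Collapse nearby same-gene calls per child
#'
#' When a child carries multiple DNMs within `window` bp in the same gene,
#' clusters are formed by transitive (single-linkage) proximity and only the
#' most severe call per cluster is kept, ties broken by smaller position.
#' Calls without a gene annotation pass through unclustered.
#'
#' @param calls data.frame with family_id, gene_id, chrom, pos and
#'   consequence/region_class columns.
#' @param window linkage distance in bp (default 100).
#' @return the collapsed data.frame.
#' @export
collapseNearby <- function(calls, window = 100L) {
  if (!nrow(calls)) return(calls)
  sev <- severityRank(if ("consequence" %in% names(calls)) calls$consequence
                      else rep(NA_character_, nrow(calls)),
                      calls$region_class)
  keyed <- !is.na(calls$gene_id)
  grp <- paste(calls$family_id, calls$gene_id)
  keep <- rep(TRUE, nrow(calls))
  kg <- grp[keyed]
  multi <- unique(kg[duplicated(kg)])
  idxByGrp <- split(which(keyed)[kg %in% multi], grp[keyed][kg %in% multi])
  for (idx in idxByGrp) {
    idx <- idx[order(calls$pos[idx])]
    gapBreak <- c(TRUE, diff(calls$pos[idx]) > window)
    cl <- cumsum(gapBreak)
    for (c0 in unique(cl)) {
      members <- idx[cl == c0]
      if (length(members) < 2L) next
      best <- members[order(-sev[members], calls$pos[members])][1L]
      keep[setdiff(members, best)] <- FALSE
    }
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
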