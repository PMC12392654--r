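# Case-control burden statistics, Fisher combination and multiple-testing
# correction.

#' Fold change of carrier fractions
#'
#' (x_case/n_case) / (x_ctrl/n_ctrl); a zero control numerator returns Inf.
#'
#' @param xCase,nCase case carriers and case subjects.
#' @param xCtrl,nCtrl control carriers and control subjects.
#' @return the ratio of fractions.
#' @export
foldChange <- function(xCase, nCase, xCtrl, nCtrl) {
  if (any(nCase <= 0) || any(nCtrl <= 0)) stop("cohort sizes must be > 0",
                                               call. = FALSE)
  if (any(xCase > nCase) || any(xCtrl > nCtrl))
    stop("carriers cannot exceed subjects", call. = FALSE)
  ifelse(xCtrl == 0, Inf, (xCase / nCase) / (xCtrl / nCtrl))
}

#' One-sided Fisher exact test for case enrichment
#'
#' Hypergeometric upper-tail probability of at least `a` case carriers for
#' the 2x2 table (a = case carriers, b = case non-carriers, c = control
#' carriers, d = control non-carriers).
#'
#' @param a,b,c,d the 2x2 cell counts.
#' @return the one-sided p-value.
#' @examples
#' fisherExactOneSided(11, 3497, 0, 2218)  # ~0.0045
#' @export
fisherExactOneSided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative",
                                   call. = FALSE)
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                     alternative = "greater")$p.value
}

#' Odds ratio with Haldane-Anscombe zero-cell correction
#'
#' (a*d)/(b*c) when no cell is zero; otherwise 0.5 is added to all four
#' cells before forming the cross-ratio.
#'
#' @inheritParams fisherExactOneSided
#' @return the (corrected) odds ratio.
#' @examples
#' oddsRatioCorrected(11, 3497, 0, 2218)  # ~14.6
#' @export
oddsRatioCorrected <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5
                                 c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

#' Fisher's combined probability test
#'
#' X = -2 * sum(log p_i) compared to chi-square with 2k degrees of freedom.
#' Zeros are clamped to 1e-300; a single p-value is returned unchanged.
#'
#' @param p vector of p-values in (0, 1].
#' @return the combined p-value.
#' @examples
#' fisherCombined(c(2.06e-11, 6.12e-4))  # ~4.15e-13
#' @export
fisherCombined <- function(p) {
  if (!length(p)) stop("need at least one p-value", call. = FALSE)
  if (any(is.na(p)) || any(p > 1) || any(p < 0))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (length(p) == 1L) return(p)
  x <- -2 * sum(log(.clampP(p)))
  pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Multiple-testing correction over a declared universe
#'
#' Bonferroni: p * m clamped at 1, with a significance flag at raw
#' p < 2.5e-6 (the exome-wide threshold for ~20,000 genes).
#' Benjamini-Hochberg: step-up q-values over the same declared universe
#' (q < 0.05 flag). NA p-values stay NA.
#'
#' @param p vector of p-values.
#' @param m declared number of tests (>= number of non-NA p-values).
#' @param bonferroniThreshold raw-p significance threshold for the flag.
#' @return data.frame with p_bonferroni, bonferroni_sig, q_fdr, fdr_sig.
#' @export
correctMultiple <- function(p, m = 20000L, bonferroniThreshold = 2.5e-6) {
  ok <- !is.na(p)
  if (m < sum(ok)) stop("declared universe smaller than number of tests",
                        call. = FALSE)
  pb <- ifelse(ok, pmin(p * m, 1), NA_real_)
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH", n = m)
  data.frame(p_bonferroni = pb,
             bonferroni_sig = ok & p < bonferroniThreshold,
             q_fdr = q, fdr_sig = ok & !is.na(q) & q < 0.05)
}

#' Gene-set carrier burden between cases and controls
#'
#' Builds the 2x2 carrier table for a gene set (a subject counts once no
#' matter how many qualifying DNMs it carries), with optional restriction
#' of qualifying DNMs to CADD>=15 sites and/or to 1 kb bins above a Gnocchi
#' threshold, then applies fold change, one-sided Fisher exact test and the
#' corrected odds ratio. A DNM-count-based mode (`unit = "dnms"`, total
#' qualifying DNMs instead of carriers, cohort size times mean DNM count as
#' denominator surrogate) is provided for sensitivity analysis.
#'
#' @param callsCase,callsCtrl annotated DNM calls for each arm.
#' @param geneSet character vector of gene ids (non-empty).
#' @param nCase,nCtrl subjects per arm.
#' @param classes region classes that qualify (default: all genic classes
#'   plus exonic/splicing; use e.g. `c("exonic", "splicing")` for coding
#'   burden).
#' @param cadd15 restrict to CADD>=15 calls.
#' @param gnocchiMin restrict to calls inside bins with Gnocchi above this
#'   value (requires `bins`).
#' @param bins GRanges bins (only needed with `gnocchiMin`).
#' @param useNearestGene count intergenic calls through their nearest gene.
#' @param unit "subjects" (carrier-based) or "dnms".
#' @return list: table (a, b, c, d), fold_change, odds_ratio, p_value.
#' @export
geneSetBurden <- function(callsCase, callsCtrl, geneSet, nCase, nCtrl,
                          classes = c("exonic", "splicing"),
                          cadd15 = FALSE, gnocchiMin = NULL, bins = NULL,
                          useNearestGene = FALSE,
                          unit = c("subjects", "dnms")) {
  unit <- match.arg(unit)
  if (!length(geneSet)) stop("empty gene set", call. = FALSE)
  qualify <- function(calls) {
    sel <- calls$region_class %in% classes
    gene <- calls$gene_id
    if (useNearestGene && "nearest_gene" %in% names(calls))
      gene <- ifelse(is.na(gene), calls$nearest_gene, gene)
    sel <- sel & !is.na(gene) & gene %in% geneSet
    if (cadd15) sel <- sel & isTRUE_v(calls$cadd15)
    if (!is.null(gnocchiMin)) {
      if (is.null(bins)) stop("gnocchiMin requires bins", call. = FALSE)
      pts <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$pos, width = 1L))
      hi <- bins[S4Vectors::mcols(bins)$gnocchi > gnocchiMin]
      sel <- sel & IRanges::overlapsAny(pts, hi, ignore.strand = TRUE)
    }
    calls[sel, , drop = FALSE]
  }
  qc <- qualify(callsCase); qt <- qualify(callsCtrl)
  if (unit == "subjects") {
    a <- length(unique(qc$family_id)); c0 <- length(unique(qt$family_id))
  } else {
    a <- nrow(qc); c0 <- nrow(qt)
  }
  b <- max(nCase - a, 0L); d <- max(nCtrl - c0, 0L)
  list(table = c(a = a, b = b, c = c0, d = d),
       fold_change = foldChange(a, nCase, c0, nCtrl),
       odds_ratio = oddsRatioCorrected(a, b, c0, d),
       p_value = fisherExactOneSided(a, b, c0, d))
}

#' Combine point-test evidence across variant classes and cohorts
#'
#' For each gene: Fisher-combine the per-cohort p-values within the coding
#' family and within the noncoding family (2k degrees of freedom across
#' cohorts), then combine the two family-level combined p-values into an
#' overall gene-level p-value.
#'
#' @param resultsList named list (one element per cohort) of
#'   [runPointTests()] outputs containing the "coding" and
#'   "noncoding_genic" families.
#' @return data.frame: gene_id, p_coding_combined, p_noncoding_combined,
#'   p_combined.
#' @export
combineAcrossCohorts <- function(resultsList) {
  pull <- function(res, fam) {
    r <- res[res$test_family == fam, c("gene_id", "p_value")]
    setNames(r$p_value, r$gene_id)
  }
  genes <- sort(unique(unlist(lapply(resultsList, function(r) r$gene_id))))
  comb <- function(fam) vapply(genes, function(g) {
    ps <- unlist(lapply(resultsList, function(r) pull(r, fam)[g]))
    ps <- ps[!is.na(ps)]
    if (!length(ps)) NA_real_ else fisherCombined(ps)
  }, numeric(1))
  pc <- comb("coding"); pn <- comb("noncoding_genic")
  overall <- vapply(seq_along(genes), function(i) {
    ps <- c(pc[i], pn[i]); ps <- ps[!is.na(ps)]
    if (!length(ps)) NA_real_ else fisherCombined(ps)
  }, numeric(1))
  data.frame(gene_id = genes, p_coding_combined = unname(pc),
             p_noncoding_combined = unname(pn), p_combined = overall,
             row.names = NULL, stringsAsFactors = FALSE)
}
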