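# Case-only Poisson enrichment tests with gene-specific expected counts.

#' Expected coding DNM count for a gene
#'
#' expected = p_gene * n_trios * 2 (two transmitted autosomal chromosomes
#' per trio).
#'
#' @param pGene per-chromosome per-generation DNM probability.
#' @param nTrios number of trios.
#' @return expected count (vectorized).
#' @examples
#' expectedCoding(1e-5, 100)       # 0.002
#' expectedCoding(7.839e-5, 3508)  # ~0.55
#' @export
expectedCoding <- function(pGene, nTrios) {
  if (any(nTrios <= 0)) stop("nTrios must be > 0", call. = FALSE)
  if (any(pGene <= 0)) stop("pGene must be > 0", call. = FALSE)
  pGene * nTrios * 2
}

#' Expected CADD>=15 noncoding DNM count for a gene (point-based model)
#'
#' The coding expected count scaled by the ratio of the gene's noncoding
#' functional length (CADD>=15 positions in the noncoding footprint) to its
#' coding length; assumes the noncoding mutation rate within a gene tracks
#' its coding rate.
#'
#' @inheritParams expectedCoding
#' @param noncodingLength noncoding functional length (positions).
#' @param codingLength coding length (bp); genes with 0 are skipped upstream.
#' @return expected count (vectorized).
#' @export
expectedNoncodingPoint <- function(pGene, nTrios, noncodingLength,
                                   codingLength) {
  if (any(codingLength <= 0)) stop("codingLength must be > 0", call. = FALSE)
  expectedCoding(pGene, nTrios) * (noncodingLength / codingLength)
}

#' Case-only Poisson tail p-value
#'
#' P(X >= observed) for X ~ Poisson(expected): the upper tail
#' ppois(observed - 1, expected, lower.tail = FALSE). observed = 0 gives 1;
#' expected = 0 with observed > 0 gives the 1e-300 clamp.
#'
#' @param observed non-negative integer count (vectorized).
#' @param expected non-negative expected count (vectorized).
#' @return p-values in (0, 1].
#' @examples
#' poissonCaseOnly(11, 0.55)
#' @export
poissonCaseOnly <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0))
    stop("observed and expected must be non-negative", call. = FALSE)
  if (any(observed != round(observed)))
    stop("observed must be integer counts", call. = FALSE)
  p <- ppois(observed - 1, expected, lower.tail = FALSE)
  p[observed == 0] <- 1
  .clampP(p)
}

#' Randomized (PIT) Poisson p-value for calibration diagnostics
#'
#' The deterministic Poisson tail p-value is discrete, so under the null it
#' is stochastically larger than uniform (strikingly so at small expected
#' counts, where most genes observe 0 and get p = 1). The randomized
#' probability integral transform p = P(X > k) + U * P(X = k), U ~ U(0,1),
#' is exactly uniform under the null and is the standard construction for
#' checking calibration of discrete tests; use it for QQ/KS diagnostics,
#' never for inference.
#'
#' @inheritParams poissonCaseOnly
#' @return randomized p-values, exactly uniform under the null.
#' @export
randomizedPoissonP <- function(observed, expected) {
  u <- runif(length(observed))
  p <- ppois(observed, expected, lower.tail = FALSE) +
    u * dpois(observed, expected)
  .clampP(p)
}

.POINT_FAMILIES <- c("coding", "missense", "lgd", "noncoding_genic",
                     "noncoding_intergenic")

.GENIC_NONCODING_CLASSES <- c("intronic", "UTR5", "UTR3", "upstream",
                              "downstream", "ncRNA_exonic", "ncRNA_intronic",
                              "ncRNA_splicing")

#' Run case-only point-based enrichment tests per gene
#'
#' For each requested test family, counts qualifying case DNMs per gene
#' (coding: exonic + splicing calls; missense; LGD; noncoding genic:
#' genic-noncoding region classes with CADD>=15; noncoding intergenic:
#' intergenic CADD>=15 calls via their nearest gene), computes the matching
#' expected count and the case-only Poisson p-value, and applies
#' Bonferroni and Benjamini-Hochberg correction over the declared test
#' universe. Every rate-table gene is reported (observed 0 gives p = 1);
#' genes carrying DNMs but missing from the rate table are reported with NA
#' expected and p (logged).
#'
#' @param calls annotated, filtered, collapsed case DNM calls.
#' @param rates mutation-rate table.
#' @param geneModels a [GeneModelSet-class] with functional lengths set for
#'   the noncoding families.
#' @param nTrios number of case trios.
#' @param families subset of coding, missense, lgd, noncoding_genic,
#'   noncoding_intergenic.
#' @param universeSize declared number of tests for correction
#'   (default 20000 genes).
#' @return data.frame: gene_id, test_family, observed, expected, p_value,
#'   p_bonferroni, bonferroni_sig, q_fdr.
#' @export
runPointTests <- function(calls, rates, geneModels, nTrios,
                          families = .POINT_FAMILIES,
                          universeSize = 20000L) {
  families <- match.arg(families, .POINT_FAMILIES, several.ok = TRUE)
  gt <- geneTable(geneModels)
  out <- list()
  for (fam in families) {
    sel <- switch(fam,
      coding = calls$region_class %in% c("exonic", "splicing"),
      missense = !is.na(calls$consequence) & calls$consequence == "missense",
      lgd = isTRUE_v(calls$is_LGD),
      noncoding_genic = calls$region_class %in% .GENIC_NONCODING_CLASSES &
        isTRUE_v(calls$cadd15),
      noncoding_intergenic = calls$region_class == "intergenic" &
        isTRUE_v(calls$cadd15))
    gene <- if (fam == "noncoding_intergenic") calls$nearest_gene[sel]
            else calls$gene_id[sel]
    gene <- gene[!is.na(gene)]
    obs <- table(gene)
    gidx <- match(rates$gene_id, gt$gene_id)
    expected <- switch(fam,
      coding = expectedCoding(rates$p_total, nTrios),
      missense = expectedCoding(rates$p_missense, nTrios),
      lgd = expectedCoding(rates$p_lgd, nTrios),
      noncoding_genic = {
        ncl <- gt$noncoding_functional_length[gidx]
        ifelse(gt$coding_length[gidx] > 0,
               expectedNoncodingPoint(rates$p_total, nTrios, ncl,
                                      gt$coding_length[gidx]), NA_real_)
      },
      noncoding_intergenic = {
        icl <- gt$intergenic_functional_length[gidx]
        ifelse(gt$coding_length[gidx] > 0,
               expectedNoncodingPoint(rates$p_total, nTrios, icl,
                                      gt$coding_length[gidx]), NA_real_)
      })
    observed <- as.integer(obs[match(rates$gene_id, names(obs))])
    observed[is.na(observed)] <- 0L
    p <- rep(NA_real_, length(observed))
    ok <- !is.na(expected)
    p[ok] <- poissonCaseOnly(observed[ok], expected[ok])
    df <- data.frame(gene_id = rates$gene_id, test_family = fam,
                     observed = observed, expected = expected, p_value = p,
                     stringsAsFactors = FALSE)
    # genes with DNMs but no rate entry: reported, no expected model
    orphan <- setdiff(names(obs), rates$gene_id)
    if (length(orphan)) {
      message("runPointTests[", fam, "]: ", length(orphan),
              " gene(s) with DNMs but no rate entry")
      df <- rbind(df, data.frame(gene_id = orphan, test_family = fam,
                                 observed = as.integer(obs[orphan]),
                                 expected = NA_real_, p_value = NA_real_))
    }
    corr <- correctMultiple(df$p_value, m = max(universeSize, sum(!is.na(df$p_value))))
    df$p_bonferroni <- corr$p_bonferroni
    df$bonferroni_sig <- corr$bonferroni_sig
    df$q_fdr <- corr$q_fdr
    out[[fam]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# treat NA as FALSE in logical selections
isTRUE_v <- function(x) !is.na(x) & x
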