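# Case-control burden statistics, Fisher combination, corrections.

test_that("fold change is the ratio of carrier fractions", {
  expect_equal(foldChange(100, 1000, 50, 1000), 2)
  expect_equal(foldChange(30, 300, 20, 200), 1)
  expect_equal(foldChange(378, 3508, 162, 2188), 1.456, tolerance = 1e-3)
  expect_identical(foldChange(5, 100, 0, 100), Inf)
  expect_error(foldChange(101, 100, 0, 100), "carriers")
})

test_that("one-sided Fisher exact equals hypergeometric enumeration", {
  hyperOracle <- function(a, b, c, d) {
    # P(X >= a) for X ~ Hypergeom(row1 = a+b draws, col1 = a+c successes)
    sum(dhyper(a:(a + c), a + c, b + d, a + b))
  }
  set.seed(9)
  for (i in 1:40) {
    m <- sample(0:25, 4, replace = TRUE)
    expect_equal(fisherExactOneSided(m[1], m[2], m[3], m[4]),
                 hyperOracle(m[1], m[2], m[3], m[4]), tolerance = 1e-10)
  }
  expect_equal(fisherExactOneSided(0, 100, 0, 100), 1)
})

test_that("odds ratios apply the Haldane-Anscombe correction only at zeros", {
  expect_equal(oddsRatioCorrected(11, 3497, 0, 2218),
               (11.5 * 2218.5) / (3497.5 * 0.5))
  expect_equal(oddsRatioCorrected(1, 1, 1, 1), 1)
  expect_equal(oddsRatioCorrected(20, 10, 5, 10), (20 * 10) / (10 * 5))
})

test_that("Fisher combination matches the closed-form series", {
  closedForm <- function(p) {   # exp(-X/2) * sum_{j<k} (X/2)^j / j!
    x <- -2 * sum(log(p)); k <- length(p)
    exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
  }
  set.seed(4)
  for (k in c(2L, 3L, 4L, 6L)) {
    for (i in 1:20) {
      p <- runif(k)^3
      expect_equal(fisherCombined(p), closedForm(p),
                   tolerance = 1e-10)
    }
  }
  expect_equal(fisherCombined(0.37), 0.37)          # k = 1 passthrough
  expect_equal(fisherCombined(c(1, 1)), 1)
  expect_error(fisherCombined(c(0.5, 1.2)), "p-values")
})

test_that("multiple-testing correction follows Bonferroni and BH", {
  out <- correctMultiple(1e-7, m = 20000L)
  expect_equal(out$p_bonferroni, 2e-3)
  expect_true(out$bonferroni_sig)                   # 1e-7 < 2.5e-6
  out2 <- correctMultiple(c(0.01, 0.02, 0.03, 0.04), m = 4L)
  expect_equal(out2$q_fdr, rep(0.04, 4))            # step-up by hand
  p <- runif(50)
  expect_true(all(correctMultiple(p, m = 50L)$p_bonferroni >= p))
  # BH q-values are invariant to input order
  set.seed(2)
  perm <- sample(50)
  q1 <- correctMultiple(p, m = 1000L)$q_fdr
  q2 <- correctMultiple(p[perm], m = 1000L)$q_fdr
  expect_equal(q1[perm], q2)
  expect_error(correctMultiple(runif(10), m = 5L), "universe smaller")
})

test_that("gene-set burden counts carriers once per subject", {
  calls <- data.frame(
    family_id = c("A", "A", "B", "C"), chrom = "chr1", pos = c(1, 5, 9, 13),
    region_class = "exonic", gene_id = c("G1", "G1", "G1", "G2"),
    cadd15 = c(TRUE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  ctrl <- calls[0, ]
  out <- geneSetBurden(calls, ctrl, c("G1"), nCase = 10, nCtrl = 10)
  expect_equal(unname(out$table["a"]), 2L)   # A and B, not A twice
  expect_identical(out$fold_change, Inf)
  out2 <- geneSetBurden(calls, ctrl, c("G1", "G2"), nCase = 10, nCtrl = 10,
                        cadd15 = TRUE)
  expect_equal(unname(out2$table["a"]), 2L)  # A via G1, C via G2
  expect_error(geneSetBurden(calls, ctrl, character(0), 10, 10), "empty")
  # count-based mode counts DNMs, not subjects
  out3 <- geneSetBurden(calls, ctrl, c("G1"), nCase = 10, nCtrl = 10,
                        unit = "dnms")
  expect_equal(unname(out3$table["a"]), 3L)
})

test_that("planted set-level enrichment is detected by the burden test", {
  cfg <- simConfig(seed = 31L, nChromosomes = 1L, chromLength = 400000L,
                   nGenes = 40L, nCaseTrios = 400L, nControlTrios = 400L,
                   dnmRate = 12, codingDnmsPerChild = 1.5,
                   decoysPerType = 0L, inheritedHetsPerChild = 0)
  ref <- generateReference(cfg)
  gm <- generateGeneModels(cfg, ref)
  ref <- imprintGeneSignals(ref, gm)
  rates <- generateMutationRates(gm, cfg)
  setGenes <- rates$gene_id[order(-rates$p_total)][1:8]
  cfg@enrichment <- setNames(rep(2, 8), setGenes)
  coh <- simulateTrioCohort(cfg, ref, gm, rates)
  res <- callDnms(cohortRecords(coh), gm, ref)
  case <- res$calls[res$calls$cohort == "case", ]
  ctrl <- res$calls[res$calls$cohort == "control", ]
  out <- geneSetBurden(case, ctrl, setGenes, cfg@nCaseTrios,
                       cfg@nControlTrios)
  expect_gt(out$fold_change, 1)
  expect_lt(out$p_value, 0.05)
})

test_that("cross-cohort combination multiplies evidence per family", {
  mk <- function(pc, pn) rbind(
    data.frame(gene_id = "G1", test_family = "coding", p_value = pc),
    data.frame(gene_id = "G1", test_family = "noncoding_genic",
               p_value = pn))
  out <- combineAcrossCohorts(list(a = mk(2.06e-11, 6.12e-4),
                                   b = mk(3.53e-5, 0.35)))
  expect_equal(out$p_coding_combined, 2.60e-14, tolerance = 0.005)
  expect_equal(out$p_noncoding_combined, 2.02e-3, tolerance = 0.005)
  expect_equal(out$p_combined,
               fisherCombined(c(out$p_coding_combined,
                                out$p_noncoding_combined)))
})
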