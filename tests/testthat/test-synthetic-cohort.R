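# Trio cohort simulation: Poisson DNM counts, truth-set conservation,
# decoy construction, VCF serialization and round trip.

test_that("per-child DNM counts follow the configured Poisson mean", {
  cfg <- simConfig(seed = 11L, nChromosomes = 1L, chromLength = 1000000L,
                   nGenes = 60L, nCaseTrios = 500L, nControlTrios = 1L,
                   dnmRate = 90, decoysPerType = 0L,
                   inheritedHetsPerChild = 0)
  ref <- generateReference(cfg)
  gm <- generateGeneModels(cfg, ref)
  rates <- generateMutationRates(gm, cfg)
  coh <- simulateTrioCohort(cfg, ref, gm, rates)
  rec <- cohortRecords(coh)
  perChild <- table(factor(rec$family_id[rec$cohort == "case"],
                           levels = sprintf("CASE%04d", 1:500)))
  se <- sqrt(90 / 500)
  expect_lt(abs(mean(perChild) - 90), 3 * se)
})

test_that("truth set is row-aligned and conserves planted DNMs", {
  fx <- smallStudy()
  coh <- fx$study@cohort
  rec <- cohortRecords(coh); tru <- cohortTruth(coh)
  expect_equal(nrow(rec), nrow(tru))
  # every planted DNM is a child-het record in exactly one family
  dnm <- rec[tru$origin == "dnm", ]
  expect_true(all(dnm$child_gt == "0/1"))
  expect_true(all(dnm$mother_gt == "0/0" & dnm$father_gt == "0/0"))
  pc <- plantedCounts(coh)
  expect_equal(sum(pc$planted),
               sum(tru$origin == "dnm" & !is.na(tru$true_gene)))
})

test_that("decoys are planted as configured and flagged in the truth set", {
  fx <- smallStudy()
  coh <- fx$study@cohort
  tru <- cohortTruth(coh)
  decoys <- table(tru$decoy_type[tru$origin == "decoy"],
                  cohortRecords(coh)$cohort[tru$origin == "decoy"])
  expect_true(all(decoys == fx$study@config@decoysPerType))
  expect_true(all(c("ad_alt", "child_gq", "parent_gq", "parent_dp", "pop_af",
                    "allele_balance", "mappability", "blacklist",
                    "parent_het", "child_hom_alt") %in% rownames(decoys)))
  gq <- cohortRecords(coh)$child_gq[tru$decoy_type %in% "child_gq"]
  expect_true(all(gq == 10L))
})

test_that("with no enrichment the case:control planted ratio is balanced", {
  fx <- smallStudy()
  pc <- plantedCounts(fx$study@cohort)
  caseN <- sum(pc$planted[pc$cohort == "case" & pc$class == "coding"])
  ctrlN <- sum(pc$planted[pc$cohort == "control" & pc$class == "coding"])
  # equal cohort sizes: binomial 99.9% interval around 0.5
  p <- caseN / (caseN + ctrlN)
  expect_lt(abs(p - 0.5), 3.3 * sqrt(0.25 / (caseN + ctrlN)))
})

test_that("unknown enrichment gene ids are rejected", {
  fx <- smallStudy()
  st <- fx$study
  cfg <- smallConfig()
  cfg@enrichment <- c(NOPE = 10)
  expect_error(simulateTrioCohort(cfg, st@reference, st@genes, st@rates),
               "unknown gene ids")
})

test_that("VCF output is byte-deterministic and round trips through readTrioVcf", {
  fx <- smallStudy()
  st <- fx$study
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohortVcfs(st@cohort, d1, st@reference)
  writeCohortVcfs(st@cohort, d2, st@reference)
  f <- list.files(d1)[1:3]
  for (fn in f)
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  rec <- cohortRecords(st@cohort)
  for (fn in f) {
    fam <- sub("\\.vcf$", "", fn)
    got <- readTrioVcf(file.path(d1, fn))
    want <- rec[rec$family_id == fam, ]
    ord <- function(x) x[order(x$chrom, x$pos, x$ref, x$alt), ]
    got <- ord(got); want <- ord(want)
    for (cc in c("chrom", "pos", "ref", "alt", "child_gt", "mother_gt",
                 "father_gt", "child_ad_ref", "child_ad_alt", "child_dp",
                 "mother_dp", "father_dp", "child_gq", "mother_gq",
                 "father_gq"))
      expect_equal(unname(as.vector(got[[cc]])),
                   unname(as.vector(want[[cc]])), label = cc)
  }
})

test_that("planted enrichment inflates the enriched gene's case counts", {
  cfg <- simConfig(seed = 21L, nChromosomes = 1L, chromLength = 300000L,
                   nGenes = 30L, nCaseTrios = 80L, nControlTrios = 80L,
                   dnmRate = 25, codingDnmsPerChild = 1.2,
                   decoysPerType = 0L, inheritedHetsPerChild = 0)
  ref <- generateReference(cfg)
  gm <- generateGeneModels(cfg, ref)
  rates <- generateMutationRates(gm, cfg)
  target <- rates$gene_id[which.max(rates$p_total)]
  cfg@enrichment <- setNames(10, target)
  coh <- simulateTrioCohort(cfg, ref, gm, rates)
  pc <- plantedCounts(coh)
  sel <- pc$gene_id == target & pc$class == "coding"
  caseN <- sum(pc$planted[sel & pc$cohort == "case"])
  ctrlN <- sum(pc$planted[sel & pc$cohort == "control"])
  expect_gt(caseN, 3 * max(ctrlN, 1))
})
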