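# Normalization, candidate detection and the eight-criterion filter chain.

.trioRow <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                     child_gt = "0/1", mother_gt = "0/0", father_gt = "0/0",
                     child_ad_ref = 15L, child_ad_alt = 15L, child_dp = 30L,
                     mother_dp = 30L, father_dp = 30L, child_gq = 60L,
                     mother_gq = 60L, father_gq = 60L) {
  data.frame(family_id = "F1", cohort = "case", chrom = chrom, pos = pos,
             ref = ref, alt = alt, child_gt = child_gt,
             mother_gt = mother_gt, father_gt = father_gt,
             child_ad_ref = child_ad_ref, child_ad_alt = child_ad_alt,
             child_dp = child_dp, mother_dp = mother_dp,
             father_dp = father_dp, child_gq = child_gq,
             mother_gq = mother_gq, father_gq = father_gq,
             stringsAsFactors = FALSE)
}

test_that("multi-allelic records split and symbolic alleles drop", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 200), collapse = "")))
  rec <- .trioRow(pos = 100L, ref = "AT", alt = "A,ATT")
  out <- normalizeVariants(rec, ref)
  expect_equal(nrow(out), 2L)
  expect_equal(out$pos, c(100L, 100L))
  rec2 <- rbind(.trioRow(alt = "*"), .trioRow(alt = "<DEL>"), .trioRow())
  expect_message(out2 <- normalizeVariants(rec2, ref), "dropped 2")
  expect_equal(nrow(out2), 1L)
})

test_that("indels left-align to the exhaustive-shift oracle in repeats", {
  s <- paste0(paste(rep("G", 20), collapse = ""),
              "ATTTTTTC", paste(rep("G", 40), collapse = ""))
  ref <- Biostrings::DNAStringSet(c(chr1 = s))
  chromStr <- s
  applyEdit <- function(pos, rf, al) paste0(
    substr(chromStr, 1, pos - 1), al,
    substr(chromStr, pos + nchar(rf), nchar(chromStr)))
  oracle <- function(pos, rf, al) {
    target <- applyEdit(pos, rf, al)
    d <- abs(nchar(rf) - nchar(al))
    for (q in 1:pos) {
      if (nchar(rf) > nchar(al)) {         # deletion
        rf2 <- substr(chromStr, q, q + d); al2 <- substr(chromStr, q, q)
      } else {                             # insertion
        rf2 <- substr(chromStr, q, q)
        al2 <- paste0(rf2, substr(target, q + 1, q + d))
      }
      if (applyEdit(q, rf2, al2) == target) return(list(pos = q, ref = rf2,
                                                        alt = al2))
    }
    stop("oracle failed")
  }
  # deletion of one T placed rightmost in the homopolymer (T run is 22-27)
  for (case in list(list(27L, "TC", "C"), list(26L, "TT", "T"),
                    list(24L, "TTT", "T"))) {
    pos <- case[[1]]; rf <- case[[2]]; al <- case[[3]]
    # convert to anchored representation the package accepts
    rec <- .trioRow(pos = pos, ref = rf, alt = al)
    out <- normalizeVariants(rec, ref)
    oc <- oracle(pos, rf, al)
    expect_equal(out$pos, oc$pos)
    expect_equal(applyEdit(out$pos, out$ref, out$alt),
                 applyEdit(oc$pos, oc$ref, oc$alt))
  }
  # an already-normalized SNV is unchanged
  snv <- .trioRow(pos = 30L, ref = "G", alt = "C")
  expect_identical(normalizeVariants(snv, ref)[, c("pos", "ref", "alt")],
                   snv[, c("pos", "ref", "alt")])
})

test_that("candidate detection requires child het and hom-ref parents", {
  rec <- rbind(.trioRow(),                                   # candidate
               .trioRow(father_gt = "0/1"),                  # parent carrier
               .trioRow(child_gt = "1/1"),                   # hom-alt child
               .trioRow(mother_gt = "./."),                  # missing parent
               .trioRow(child_gt = "0/0"))                   # no alt
  out <- detectCandidateDnms(rec)
  expect_identical(out$candidate, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(out$exclude_reason[2:5],
                   c("parent_carrier", "child_hom_alt", "parent_missing",
                     "child_no_alt"))
})

test_that("allele balance is the alt-read fraction", {
  expect_equal(alleleBalance(10, 10), 0.5)
  expect_equal(alleleBalance(30, 10), 0.25)
  expect_equal(alleleBalance(3, 9), 0.75)
  expect_true(is.na(alleleBalance(0, 0)))
})

test_that("filter boundaries behave as specified", {
  th <- dnmFilterThresholds()
  cand <- rbind(
    .trioRow(child_ad_alt = 5L, child_ad_ref = 11L, child_dp = 16L),  # ad
    .trioRow(father_dp = 8L),                    # DP > 8 is exclusive
    .trioRow(child_ad_ref = 30L, child_ad_alt = 10L, child_dp = 40L), # AB=0.25
    .trioRow(child_gq = 24L),
    .trioRow(mother_gq = 19L),
    .trioRow())
  out <- applyDnmFilters(cand, th)
  expect_equal(out$fail_reasons[1], "ad_alt")
  expect_equal(out$fail_reasons[2], "parent_dp")
  expect_equal(out$filter_status[3], "pass")     # inclusive AB bound
  expect_equal(out$fail_reasons[4], "child_gq")
  expect_equal(out$fail_reasons[5], "parent_gq")
  expect_equal(out$filter_status[6], "pass")
})

test_that("all violated criteria accumulate and AF/mask/blacklist work", {
  th <- dnmFilterThresholds()
  cand <- .trioRow(child_ad_alt = 5L, child_ad_ref = 50L, child_dp = 55L,
                   child_gq = 10L)
  out <- applyDnmFilters(cand, th)
  expect_setequal(strsplit(out$fail_reasons, ";")[[1]],
                  c("ad_alt", "child_gq", "allele_balance"))
  af <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                   af = 0.01)
  out2 <- applyDnmFilters(.trioRow(), th, afTable = af)
  expect_equal(out2$fail_reasons, "pop_af")
  # sub-threshold and missing AF both pass
  af$af <- 0.0005
  expect_equal(applyDnmFilters(.trioRow(), th, afTable = af)$filter_status,
               "pass")
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90L, 110L))
  expect_equal(applyDnmFilters(.trioRow(), th, mask = mask)$fail_reasons,
               "mappability")
  bl <- cbind(.trioRow(), gene_id = "HLA_G0001")
  expect_equal(applyDnmFilters(bl, th)$fail_reasons, "blacklist")
  expect_error(applyDnmFilters(.trioRow(), th,
    mask = GenomicRanges::GRanges("chr1", IRanges::IRanges(100L, 90L))))
})

test_that("filters partition candidates and are idempotent and monotone", {
  fx <- smallCalled()
  cand <- fx$candidates
  expect_equal(sum(cand$filter_status == "pass") +
               sum(cand$filter_status == "fail"), nrow(cand))
  # idempotence on the pass set
  again <- applyDnmFilters(fx$calls, dnmFilterThresholds(),
                           mask = smallStudy()$study@mask,
                           afTable = smallStudy()$study@afTable)
  expect_true(all(again$filter_status == "pass"))
  # loosening a threshold never decreases the pass count
  loose <- applyDnmFilters(cand, dnmFilterThresholds(minChildGq = 10L),
                           mask = smallStudy()$study@mask,
                           afTable = smallStudy()$study@afTable)
  expect_gte(sum(loose$filter_status == "pass"),
             sum(cand$filter_status == "pass"))
})

test_that("collapse keeps the most severe call per transitive 100 bp cluster", {
  mk <- function(pos, cons, cls) data.frame(
    family_id = "F1", gene_id = "G1", chrom = "chr1", pos = pos,
    consequence = cons, region_class = cls, stringsAsFactors = FALSE)
  # LGD + intronic 50 bp apart: keep the LGD
  x <- rbind(mk(100L, "stopgain", "exonic"), mk(150L, NA, "intronic"))
  expect_equal(collapseNearby(x)$pos, 100L)
  # two missense 150 bp apart: keep both
  y <- rbind(mk(100L, "missense", "exonic"), mk(250L, "missense", "exonic"))
  expect_equal(nrow(collapseNearby(y)), 2L)
  # transitive chain a-b 80, b-c 80 (a-c 160): one cluster, keep the missense
  z <- rbind(mk(100L, NA, "intronic"), mk(180L, "missense", "exonic"),
             mk(260L, NA, "intronic"))
  out <- collapseNearby(z)
  expect_equal(out$pos, 180L)
  # brute-force single-linkage clustering oracle on a random instance
  set.seed(42)
  pos <- sort(sample.int(2000L, 30L))
  w <- rbind(do.call(rbind, lapply(pos, function(p)
    mk(p, sample(c("missense", NA), 1), "intronic"))))
  w$consequence[1] <- "missense"
  got <- collapseNearby(w)
  adj <- abs(outer(pos, pos, "-")) <= 100
  comp <- seq_along(pos)
  repeat {   # transitive closure by label propagation
    new <- vapply(seq_along(pos), function(i) min(comp[adj[i, ]]), integer(1))
    if (identical(new, comp)) break
    comp <- new
  }
  expectKeep <- vapply(unique(comp), function(cp) {
    idx <- which(comp == cp)
    sev <- severityRank(w$consequence[idx], w$region_class[idx])
    idx[order(-sev, pos[idx])][1]
  }, integer(1))
  expect_setequal(got$pos, pos[sort(expectKeep)])
  # different children never cluster together
  v <- rbind(mk(100L, NA, "intronic"), mk(150L, NA, "intronic"))
  v$family_id <- c("F1", "F2")
  expect_equal(nrow(collapseNearby(v)), 2L)
})

test_that("corrupted VCFs are rejected with a parse error", {
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "chr1\t100"), bad)
  expect_error(readTrioVcf(bad), "failed to parse VCF")
})
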