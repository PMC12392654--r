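# End-to-end orchestration: simulate -> call -> annotate -> test -> combine,
# with per-stage logging, output tables and a JSON manifest.

#' Call DNMs from trio records through the full filter chain
#'
#' Normalization, candidate detection (child het, parents hom-ref),
#' region/gene annotation, the eight-criterion filter chain, and the 100 bp
#' same-gene collapse.
#'
#' @param records trio variant records (from [readTrioVcf()] or
#'   [cohortRecords()]).
#' @param geneModels a [GeneModelSet-class].
#' @param reference DNAStringSet.
#' @param thresholds from [dnmFilterThresholds()].
#' @param mask GRanges low-mappability mask or NULL.
#' @param afTable population allele-frequency table or NULL.
#' @param scores optional score track attached to the calls.
#' @return list: `calls` (passing, collapsed, annotated DNM calls),
#'   `candidates` (all candidates with filter status), `records`
#'   (normalized records with candidate status).
#' @export
callDnms <- function(records, geneModels, reference,
                     thresholds = dnmFilterThresholds(), mask = NULL,
                     afTable = NULL, scores = NULL) {
  records <- normalizeVariants(records, reference)
  records <- detectCandidateDnms(records)
  cand <- records[records$candidate, , drop = FALSE]
  cand <- annotateCalls(cand, geneModels, reference, scores)
  cand <- applyDnmFilters(cand, thresholds, mask = mask, afTable = afTable)
  pass <- cand[cand$filter_status == "pass", , drop = FALSE]
  pass <- collapseNearby(pass, window = thresholds$collapseWindowBp)
  list(calls = pass, candidates = cand, records = records)
}

#' Summarize a cohort's DNM calls, Table-2 style
#'
#' Counts of coding (exonic + splicing), LGD, missense, noncoding genic and
#' intergenic DNMs, their CADD>=15 subsets, and per-trio means.
#'
#' @param calls annotated DNM calls for one cohort arm.
#' @param nTrios trios in the arm.
#' @return one-row data.frame of counts and per-trio means.
#' @export
summarizeCohort <- function(calls, nTrios) {
  coding <- calls$region_class %in% c("exonic", "splicing")
  genic <- calls$region_class %in% .GENIC_NONCODING_CLASSES
  inter <- calls$region_class == "intergenic"
  c15 <- if ("cadd15" %in% names(calls)) isTRUE_v(calls$cadd15)
         else rep(NA, nrow(calls))
  data.frame(
    n_trios = nTrios,
    coding_dnms = sum(coding),
    lgd_dnms = sum(isTRUE_v(calls$is_LGD)),
    missense_dnms = sum(isTRUE_v(calls$consequence == "missense")),
    coding_per_trio = round(sum(coding) / nTrios, 2),
    noncoding_dnms = sum(genic | inter),
    noncoding_genic = sum(genic),
    noncoding_intergenic = sum(inter),
    noncoding_cadd15 = sum((genic | inter) & c15, na.rm = TRUE),
    genic_cadd15 = sum(genic & c15, na.rm = TRUE),
    intergenic_cadd15 = sum(inter & c15, na.rm = TRUE),
    noncoding_per_trio = round(sum(genic | inter) / nTrios, 2))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' simulate -> call-dnm -> annotate -> test-point -> test-segment -> burden
#' -> combine -> report. Writes dnms.tsv, annotated.tsv, point.tsv,
#' segment.tsv, burden.tsv, combined.tsv, summary.tsv and manifest.json to
#' `outDir`. Any stage failure aborts with an error naming the stage.
#'
#' @param config a [SimConfig-class] (or path to a YAML file of
#'   [simConfig()] arguments).
#' @param outDir output directory.
#' @param vcfDir optional directory of per-family VCFs to call from (the
#'   round-trip path); default calls from the in-memory simulated records.
#' @param writeInputs also serialize the simulated inputs under
#'   `outDir/inputs`.
#' @return invisible list of all result tables plus the study object.
#' @export
runFullAnalysis <- function(config, outDir, vcfDir = NULL,
                            writeInputs = FALSE) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(simConfig, args)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage \"%s\" failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages[[name]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 2)
    res
  }

  study <- stage("simulate", simulateStudy(
    config, dir = if (writeInputs) file.path(outDir, "inputs") else NULL))
  gm <- stage("annotate-lengths", {
    gm <- noncodingFunctionalLength(study@genes, study@scores)
    intergenicFunctionalLength(gm, study@scores)
  })

  records <- stage("call-dnm", {
    if (!is.null(vcfDir)) {
      paths <- list.files(vcfDir, pattern = "\\.vcf$", full.names = TRUE)
      famCohort <- unique(study@cohort@records[, c("family_id", "cohort")])
      do.call(rbind, lapply(paths, function(p) {
        fam <- sub("\\.vcf$", "", basename(p))
        readTrioVcf(p, familyId = fam,
                    cohort = famCohort$cohort[match(fam, famCohort$family_id)])
      }))
    } else cohortRecords(study@cohort)
  })
  called <- stage("call-dnm", callDnms(
    records, gm, study@reference, mask = study@mask,
    afTable = study@afTable, scores = study@scores))
  calls <- called$calls
  caseCalls <- calls[calls$cohort == "case", , drop = FALSE]
  ctrlCalls <- calls[calls$cohort == "control", , drop = FALSE]

  point <- stage("test-point", runPointTests(
    caseCalls, study@rates, gm, config@nCaseTrios))
  segment <- stage("test-segment", rbind(
    runSegmentTest(caseCalls, study@bins, gm, "genic"),
    runSegmentTest(caseCalls, study@bins, gm, "intergenic")))
  burden <- stage("burden", {
    rows <- lapply(names(study@geneSets), function(nm) {
      gs <- study@geneSets[[nm]]
      if (!length(gs)) return(NULL)
      cod <- geneSetBurden(caseCalls, ctrlCalls, gs, config@nCaseTrios,
                           config@nControlTrios)
      nc <- geneSetBurden(caseCalls, ctrlCalls, gs, config@nCaseTrios,
                          config@nControlTrios,
                          classes = .GENIC_NONCODING_CLASSES, cadd15 = TRUE)
      data.frame(gene_set = nm, test = c("coding", "noncoding_cadd15"),
                 case_carriers = c(cod$table["a"], nc$table["a"]),
                 control_carriers = c(cod$table["c"], nc$table["c"]),
                 fold_change = c(cod$fold_change, nc$fold_change),
                 odds_ratio = c(cod$odds_ratio, nc$odds_ratio),
                 p_value = c(cod$p_value, nc$p_value))
    })
    do.call(rbind, rows)
  })
  combined <- stage("combine", combineAcrossCohorts(list(main = point)))
  summaryTab <- stage("report", rbind(
    cbind(cohort = "case", summarizeCohort(caseCalls, config@nCaseTrios)),
    cbind(cohort = "control", summarizeCohort(ctrlCalls, config@nControlTrios))))

  paths <- c(dnms = "dnms.tsv", annotated = "annotated.tsv",
             point = "point.tsv", segment = "segment.tsv",
             burden = "burden.tsv", combined = "combined.tsv",
             summary = "summary.tsv")
  writeTsv(called$candidates, file.path(outDir, paths["dnms"]), "dnm_calls")
  writeTsv(calls, file.path(outDir, paths["annotated"]), "annotated_dnms")
  writeTsv(point, file.path(outDir, paths["point"]), "point_results")
  writeTsv(segment, file.path(outDir, paths["segment"]), "segment_results")
  writeTsv(burden, file.path(outDir, paths["burden"]), "burden_results")
  writeTsv(combined, file.path(outDir, paths["combined"]), "combined_results")
  writeTsv(summaryTab, file.path(outDir, paths["summary"]), "cohort_summary")
  digests <- vapply(file.path(outDir, paths), function(p)
    unname(tools::md5sum(p)), character(1))
  manifest <- list(
    tool = "DNMburden",
    version = as.character(utils::packageVersion("DNMburden")),
    seed = config@seed,
    config = list(n_case_trios = config@nCaseTrios,
                  n_control_trios = config@nControlTrios,
                  n_genes = config@nGenes,
                  genome_bp = sum(Biostrings::width(study@reference)),
                  dnm_rate = config@dnmRate),
    outputs = as.list(setNames(digests, paths)),
    row_counts = list(candidates = nrow(called$candidates),
                      calls = nrow(calls), point = nrow(point),
                      segment = nrow(segment)),
    stage_seconds = stages,
    wall_clock_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(study = study, geneModels = gm, calls = calls,
                 candidates = called$candidates, point = point,
                 segment = segment, burden = burden, combined = combined,
                 summary = summaryTab, manifest = manifest))
}
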