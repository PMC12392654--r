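# Per-gene de novo mutation-rate table (Samocha-style probabilities).

#' Generate a per-gene mutation-rate table
#'
#' Per-gene total, missense and LGD (likely gene disrupting) DNM
#' probabilities per chromosome per generation. Rates are proportional to
#' coding length times a log-normal gene factor (sd 0.45), reproducing the
#' strong length-rate correlation seen in real rate tables, and are scaled
#' so that the cohort-wide mean coding DNM count per child equals
#' `codingDnmsPerChild` (sum over genes of 2*p_total). ncRNA genes and
#' blacklisted (HLA/MUC-prefixed) genes carry no entry.
#'
#' @param geneModels a [GeneModelSet-class].
#' @param config a [SimConfig-class].
#' @return data.frame with gene_id, p_total, p_missense, p_lgd.
#' @export
generateMutationRates <- function(geneModels, config) {
  g <- geneModels@genes
  use <- g$is_coding & !grepl("^(HLA|MUC)", g$gene_id)
  len <- g$coding_length[use]
  .withStageSeed(config@seed, "rates", {
    raw <- len * rlnorm(sum(use), meanlog = 0, sdlog = 0.25)
    p_total <- raw / sum(raw) * (config@codingDnmsPerChild / 2)
    fm <- rbeta(sum(use), 60, 37.7)   # missense fraction ~ 0.61
    fl <- rbeta(sum(use), 10, 81)     # LGD fraction ~ 0.11
    data.frame(gene_id = g$gene_id[use],
               p_total = p_total,
               p_missense = p_total * fm,
               p_lgd = p_total * fl,
               stringsAsFactors = FALSE)
  })
}

#' Write the mutation-rate table
#' @param rates data.frame from [generateMutationRates()].
#' @param path output file.
#' @export
writeRateTable <- function(rates, path) writeTsv(rates, path, "mutation_rates")
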