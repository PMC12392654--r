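#' Generate a synthetic reference genome
#'
#' Draws `nChromosomes` independent sequences of i.i.d. bases (A/C/G/T,
#' GC fraction 0.42) under the "reference" stage of the config seed.
#' Deterministic: the same config always yields the same sequences.
#'
#' @param config a [SimConfig-class].
#' @return A [Biostrings::DNAStringSet] named chr1, chr2, ...
#' @examples
#' ref <- generateReference(simConfig(seed = 1, nChromosomes = 1L,
#'                                    chromLength = 10000L, nGenes = 2L))
#' @export
generateReference <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .withStageSeed(config@seed, "reference", {
    probs <- c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)
    seqs <- vapply(seq_len(config@nChromosomes), function(i) {
      paste(sample(names(probs), config@chromLength, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1))
    ref <- Biostrings::DNAStringSet(seqs)
    names(ref) <- paste0("chr", seq_len(config@nChromosomes))
    ref
  })
}

#' Write the reference as FASTA
#'
#' @param reference a DNAStringSet.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeReferenceFasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path, width = 70L)
  invisible(path)
}

# seqinfo shared by all GRanges built against a reference
.refSeqinfo <- function(reference) {
  GenomeInfoDb::Seqinfo(seqnames = names(reference),
                        seqlengths = Biostrings::width(reference))
}
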