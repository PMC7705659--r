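# Small constructed fixtures shared across test files.

# a gene table for one chromosome with n genes in the given id order
fixture_chromosome <- function(ids, seq_id = "chr1", strand = "+") {
  n <- length(ids)
  data.frame(
    gene_id = ids, seq_id = seq_id,
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = strand, rank = seq_len(n) - 1L,
    stringsAsFactors = FALSE
  )
}

# one-to-one hits between two id vectors
fixture_hits <- function(ids_a, ids_b, score = 10) {
  data.frame(
    query_id = ids_a, subject_id = ids_b,
    score = score, e_value = 1e-30,
    stringsAsFactors = FALSE
  )
}

# random CDS (with start/stop codons) of the given codon count
fixture_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  stops <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
  paste0(
    c("ATG", sample(sense, n_codons - 2L, replace = TRUE), sample(stops, 1L)),
    collapse = ""
  )
}
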