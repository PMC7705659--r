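# Assembly and annotation summary statistics (the Table-1-style report) and
# a k-mer histogram genome-size estimator.

#' Assembly summary statistics
#'
#' N50 is the smallest length in the minimal descending-sorted prefix of
#' scaffold lengths whose sum reaches half the assembly total; L50 is that
#' prefix's size. GC is computed over unambiguous bases only. The anchored
#' fraction is the share of total length on the named chromosome-scale
#' sequences.
#'
#' @param seqs a named `DNAStringSet`, a named character vector of sequences,
#'   or a named numeric vector of sequence lengths (GC reported as NA then)
#' @param chromosome_ids character vector of sequence names counted as
#'   anchored (default none)
#' @return list: `n_scaffolds`, `total_bp`, `longest_bp`, `N50`, `L50`,
#'   `gc_fraction`, `anchored_bp`, `anchored_fraction`
#' @export
assembly_stats <- function(seqs, chromosome_ids = character(0)) {
  if (is.numeric(seqs)) {
    lens <- seqs
    gc <- NA_real_
  } else {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
    fr <- Biostrings::letterFrequency(seqs, c("G", "C", "A", "T"))
    gc <- sum(fr[, c("G", "C")]) / sum(fr)
  }
  if (length(lens) == 0 || any(lens < 1)) stop("empty or invalid FASTA")
  srt <- sort(lens, decreasing = TRUE)
  csum <- cumsum(as.numeric(srt))
  l50 <- which(csum >= sum(as.numeric(lens)) / 2)[1]
  anchored <- sum(as.numeric(lens[names(lens) %in% chromosome_ids]))
  list(
    n_scaffolds = length(lens),
    total_bp = sum(as.numeric(lens)),
    longest_bp = max(lens),
    N50 = unname(srt[l50]),
    L50 = unname(l50),
    gc_fraction = gc,
    anchored_bp = anchored,
    anchored_fraction = anchored / sum(as.numeric(lens))
  )
}

#' Annotation summary statistics
#'
#' @param genes data.frame with `seq_id`, `start`, `end`, `exon_count` and
#'   optionally `cds` (for the mean CDS length)
#' @param chromosome_ids sequence names counted as chromosome-placed
#' @return list: `n_genes`, `mean_gene_len`, `mean_cds_len`, `n_exons`,
#'   `mean_exons_per_gene`, `n_on_chromosomes`, `pct_on_chromosomes`,
#'   `pct_on_scaffolds` (percentages unrounded; print at 2 dp)
#' @export
annotation_stats <- function(genes, chromosome_ids = character(0)) {
  n <- nrow(genes)
  if (n == 0) stop("no genes")
  n_exons <- sum(genes$exon_count)
  on_chr <- sum(genes$seq_id %in% chromosome_ids)
  list(
    n_genes = n,
    mean_gene_len = mean(genes$end - genes$start + 1),
    mean_cds_len = if (!is.null(genes$cds)) mean(nchar(genes$cds)) else
      NA_real_,
    n_exons = n_exons,
    mean_exons_per_gene = n_exons / n,
    n_on_chromosomes = on_chr,
    pct_on_chromosomes = 100 * on_chr / n,
    pct_on_scaffolds = 100 * (n - on_chr) / n
  )
}

#' Genome-size estimate from a k-mer depth histogram
#'
#' Peak-ratio method: the error cutoff is the first interior local minimum of
#' count vs depth; the homozygous peak is the modal depth beyond the cutoff;
#' the estimate is the depth-weighted k-mer mass at or beyond the cutoff
#' divided by the peak depth.
#'
#' @param histogram data.frame with `depth` (>= 1, ascending) and `count`
#' @return list: `genome_size_bp`, `peak_depth`, `error_cutoff`
#' @export
kmer_genome_size <- function(histogram) {
  stopifnot(all(c("depth", "count") %in% names(histogram)))
  h <- histogram[order(histogram$depth), ]
  if (any(h$depth < 1)) stop("depths must be >= 1")
  cnt <- h$count
  n <- length(cnt)
  cutoff_idx <- NA_integer_
  for (i in 2:(n - 1)) {
    if (cnt[i] <= cnt[i - 1] && cnt[i] <= cnt[i + 1] &&
        (cnt[i] < cnt[i - 1] || cnt[i] < cnt[i + 1])) {
      cutoff_idx <- i
      break
    }
  }
  if (is.na(cutoff_idx)) {
    stop("no error/signal separation: histogram has no interior local minimum")
  }
  sig <- h[cutoff_idx:n, , drop = FALSE]
  peak_depth <- sig$depth[which.max(sig$count)]
  est <- sum(as.numeric(sig$depth) * as.numeric(sig$count)) / peak_depth
  list(genome_size_bp = est, peak_depth = peak_depth,
       error_cutoff = h$depth[cutoff_idx])
}
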