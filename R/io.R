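# Readers and writers for the standard interchange formats: FASTA (CDS and
# protein) and GFF3 via Biostrings/rtracklayer, the 12-column tabular
# homology-hit format, block files and plain TSV truth tables.

#' Write CDS and protein FASTA for a simulated/parsed gene table
#'
#' @param genes gene data.frame with `gene_id` and `cds`
#' @param cds_path,protein_path output paths (NULL to skip either)
#' @return invisibly, the translated proteins (named character)
#' @export
write_gene_fasta <- function(genes, cds_path = NULL, protein_path = NULL) {
  cds <- stats::setNames(genes$cds, genes$gene_id)
  if (!is.null(cds_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), cds_path)
  }
  prot <- vapply(cds, translate_cds, character(1))
  if (!is.null(protein_path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot), protein_path)
  }
  invisible(prot)
}

#' Write gene models as GFF3
#'
#' One `gene` feature per row, 1-based inclusive coordinates, `ID` attribute
#' carrying the gene id.
#'
#' @param genes gene data.frame (`gene_id`, `seq_id`, `start`, `end`,
#'   `strand`)
#' @param path output path
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seq_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "wgdclock"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports `gene` features and assigns each gene its 0-based ordinal rank
#' among the genes of its sequence sorted by start.
#'
#' @param path GFF3 file
#' @return gene data.frame `gene_id`, `seq_id`, `start`, `end`, `strand`,
#'   `rank`
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  df <- data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$seq_id, df$start), ]
  df$rank <- stats::ave(seq_len(nrow(df)), df$seq_id,
                        FUN = seq_along) - 1L
  rownames(df) <- NULL
  df
}

#' Add 0-based start-order ranks to a gene table
#' @param genes gene data.frame with `seq_id` and `start`
#' @return the table sorted by (seq_id, start) with a `rank` column
#' @export
assign_ranks <- function(genes) {
  genes <- genes[order(genes$seq_id, genes$start), ]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$seq_id,
                           FUN = seq_along) - 1L
  rownames(genes) <- NULL
  genes
}

#' Read a 12-column tabular homology hit file
#'
#' The de-facto tabular alignment standard: query, subject, %identity,
#' length, mismatches, gapopens, qstart, qend, sstart, send, evalue,
#' bitscore.
#'
#' @param path tab-delimited file, no header
#' @return data.frame with the 12 columns plus the package-standard aliases
#'   `query_id`, `subject_id`, `e_value`, `score`
#' @export
read_hit_table <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatches", "gapopens",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE)
  df$query_id <- df$query
  df$subject_id <- df$subject
  df$e_value <- df$evalue
  df$score <- df$bitscore
  df
}

#' Write hits in the 12-column tabular format
#' @param hits data.frame with `query_id`, `subject_id`, `score`, `e_value`
#'   (placeholder values are written for the alignment-coordinate columns)
#' @param path output path
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(
    query = hits$query_id, subject = hits$subject_id, pident = NA,
    length = NA, mismatches = NA, gapopens = NA, qstart = NA, qend = NA,
    sstart = NA, send = NA, evalue = hits$e_value, bitscore = hits$score
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write collinear blocks to a block file
#'
#' One header line per block (`# id seq_a seq_b orientation score
#' n_anchors`) followed by one tab-separated anchor per line.
#'
#' @param blocks list of `collinear_block`
#' @param path output path
#' @export
write_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    cat(sprintf("# %s\t%s\t%s\t%s\t%.3f\t%d\n", b$block_id, b$seq_pair[1],
                b$seq_pair[2], b$orientation, b$score, b$n_anchors),
        file = con)
    utils::write.table(b$anchors, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a block file written by [write_blocks()]
#' @param path block file
#' @return list of `collinear_block`
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush_block <- function(cur) {
    if (is.null(cur)) return(NULL)
    anc <- do.call(rbind, lapply(cur$anchor_lines, function(l) {
      f <- strsplit(l, "\t")[[1]]
      data.frame(gene_a = f[1], gene_b = f[2], rank_a = as.integer(f[3]),
                 rank_b = as.integer(f[4]), stringsAsFactors = FALSE)
    }))
    structure(
      list(block_id = cur$block_id, seq_pair = cur$seq_pair,
           orientation = cur$orientation, score = cur$score,
           n_anchors = nrow(anc), anchors = anc),
      class = "collinear_block"
    )
  }
  for (l in lines) {
    if (startsWith(l, "# ")) {
      b <- flush_block(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      f <- strsplit(sub("^# ", "", l), "\t")[[1]]
      cur <- list(block_id = f[1], seq_pair = c(f[2], f[3]),
                  orientation = f[4], score = as.numeric(f[5]),
                  anchor_lines = character(0))
    } else if (nzchar(l)) {
      cur$anchor_lines <- c(cur$anchor_lines, l)
    }
  }
  b <- flush_block(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write a data.frame as TSV
#' @param df data.frame
#' @param path output path
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path
#' @return data.frame
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
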