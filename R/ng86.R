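# Protein-guided codon alignment and NG86 Ka/Ks estimation.

#' Align a gene pair at the codon level
#'
#' Globally aligns the two proteins (BLOSUM62, affine gaps) and back-translates
#' the alignment onto the coding sequences codon by codon, producing gap-aware
#' codon strings of equal aligned length (gaps in whole-codon units).
#'
#' @param protein_a,protein_b amino-acid strings (no terminal stop)
#' @param cds_a,cds_b coding sequences; must translate to the proteins
#'   (a terminal stop codon on the CDS is allowed and dropped)
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment
#' @return a `codon_alignment`: list with `codons_a`, `codons_b` (character
#'   vectors of aligned codons, `"---"` for gaps) and `pair`
#' @examples
#' aln <- align_pair("MK", "MK", "ATGAAA", "ATGAAG")
#' aln$codons_a
#' @export
align_pair <- function(protein_a, protein_b, cds_a, cds_b,
                       gap_opening = 10, gap_extension = 0.5) {
  cds_a <- .strip_terminal_stop(cds_a)
  cds_b <- .strip_terminal_stop(cds_b)
  .check_cds_protein(cds_a, protein_a, "A")
  .check_cds_protein(cds_b, protein_b, "B")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  ia <- ib <- 0L
  n <- length(ap)
  out_a <- out_b <- character(n)
  for (i in seq_len(n)) {
    if (ap[i] == "-") {
      out_a[i] <- "---"
    } else {
      ia <- ia + 1L
      out_a[i] <- cod_a[ia]
    }
    if (as_[i] == "-") {
      out_b[i] <- "---"
    } else {
      ib <- ib + 1L
      out_b[i] <- cod_b[ib]
    }
  }
  structure(
    list(codons_a = out_a, codons_b = out_b,
         pair = c(NA_character_, NA_character_), score = Biostrings::score(pa)),
    class = "codon_alignment"
  )
}

.strip_terminal_stop <- function(cds) {
  cod <- split_codons(cds)
  if (length(cod) && Biostrings::GENETIC_CODE[cod[length(cod)]] == "*") {
    cds <- substr(cds, 1L, nchar(cds) - 3L)
  }
  cds
}

.check_cds_protein <- function(cds, protein, label) {
  tr <- translate_cds(cds)
  if (!identical(tr, toupper(protein))) {
    stop("CDS ", label, " does not translate to its protein (", tr,
         " vs ", protein, ")")
  }
  if (grepl("\\*", substr(tr, 1, nchar(tr)))) {
    stop("internal stop codon in CDS ", label)
  }
}

# Gapless fast path for codon alignment: when the two CDS have equal length
# and their direct positional amino-acid identity is high (>= 40%), the
# affine-gap global protein alignment is the gapless diagonal, so the codon
# columns can be paired directly. Returns NULL when the fast path does not
# apply (caller falls back to align_pair()).
.codon_align_fast <- function(cds_a, cds_b, min_identity = 0.4) {
  cds_a <- .strip_terminal_stop(cds_a)
  cds_b <- .strip_terminal_stop(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) return(NULL)
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  gc <- Biostrings::GENETIC_CODE
  if (mean(gc[ca] == gc[cb]) < min_identity) return(NULL)
  structure(
    list(codons_a = ca, codons_b = cb,
         pair = c(NA_character_, NA_character_), score = NA_real_),
    class = "codon_alignment"
  )
}

#' NG86 synonymous/nonsynonymous substitution estimate for a codon alignment
#'
#' Implements the Nei-Gojobori (1986) counting method: fractional
#' synonymous/nonsynonymous site counts per codon (changes to stop codons
#' excluded from both numerator and denominator), differences averaged with
#' equal weight over all minimal mutational pathways between differing codons
#' (pathways through stop codons excluded), Jukes-Cantor correction of the
#' proportions. Site counts are averaged between the two sequences. Codon
#' columns containing a gap or an ambiguous nucleotide are dropped pairwise.
#'
#' @param aln a `codon_alignment` from [align_pair()], or a list with
#'   `codons_a`/`codons_b` character vectors of equal length
#' @param min_codons minimum number of ungapped, unambiguous codon columns for
#'   a valid estimate (default 30)
#' @return one-row data.frame: `S`, `N` (sites), `Sd`, `Nd` (differences),
#'   `ps`, `pn`, `Ks`, `Ka`, `omega` (Ka/Ks), `n_codons`, `valid`, `reason`
#' @examples
#' aln <- list(codons_a = c("GAA", "ATG"), codons_b = c("GAG", "ATG"))
#' ng86(aln, min_codons = 1)
#' @export
ng86 <- function(aln, min_codons = 30) {
  tb <- ng86_tables()
  ca <- toupper(aln$codons_a)
  cb <- toupper(aln$codons_b)
  stopifnot(length(ca) == length(cb))
  ok <- ca %in% rownames(tb$sd) & cb %in% rownames(tb$sd) &
    !is.na(tb$sites[ca]) & !is.na(tb$sites[cb])
  ca <- ca[ok]
  cb <- cb[ok]
  n_codons <- length(ca)
  rec <- function(S, N, Sd, Nd, valid, reason) {
    ps <- if (valid && S > 0) Sd / S else NA_real_
    pn <- if (valid && N > 0) Nd / N else NA_real_
    jc <- function(p) {
      if (is.na(p)) return(NA_real_)
      if (p >= 3 / 4) return(NA_real_)
      -0.75 * log(1 - 4 * p / 3)
    }
    Ks <- jc(ps)
    Ka <- jc(pn)
    if (valid && (is.na(Ks))) {
      valid <- FALSE
      reason <- "saturated"
    }
    data.frame(
      S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
      Ks = Ks, Ka = Ka,
      omega = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
      n_codons = n_codons, valid = valid, reason = reason,
      stringsAsFactors = FALSE
    )
  }
  if (n_codons < min_codons) {
    return(rec(NA_real_, NA_real_, NA_real_, NA_real_, FALSE, "too_short"))
  }
  S <- (sum(tb$sites[ca]) + sum(tb$sites[cb])) / 2
  N <- 3 * n_codons - S
  idx <- cbind(match(ca, rownames(tb$sd)), match(cb, colnames(tb$sd)))
  Sd <- sum(tb$sd[idx])
  Nd <- sum(tb$nd[idx])
  if (S <= 0) {
    return(rec(S, N, Sd, Nd, FALSE, "no_synonymous_sites"))
  }
  rec(S, N, Sd, Nd, TRUE, "ok")
}

#' Ka/Ks for every anchor of a set of collinear blocks
#'
#' Runs [align_pair()] + [ng86()] on each anchored gene pair; anchors whose
#' CDS is missing or fails codon-structure checks are skipped and counted.
#'
#' @param blocks list of `collinear_block` objects (see
#'   [detect_collinear_blocks()])
#' @param cds_a,cds_b named character vectors of coding sequences for the two
#'   genomes (names = gene ids)
#' @param min_codons passed to [ng86()]
#' @return list with `records` (data.frame, one row per scored anchor:
#'   `block_id`, `gene_a`, `gene_b` + the [ng86()] columns), `block_median_ks`
#'   (data.frame `block_id`, `n_valid`, `median_ks`) and `n_skipped`
#' @export
ks_for_blocks <- function(blocks, cds_a, cds_b, min_codons = 30) {
  rows <- list()
  skipped <- 0L
  for (blk in blocks) {
    for (i in seq_len(nrow(blk$anchors))) {
      ga <- blk$anchors$gene_a[i]
      gb <- blk$anchors$gene_b[i]
      sa <- if (ga %in% names(cds_a)) cds_a[[ga]] else NULL
      sb <- if (gb %in% names(cds_b)) cds_b[[gb]] else NULL
      if (is.null(sa) || is.null(sb) || is.na(sa) || is.na(sb)) {
        skipped <- skipped + 1L
        next
      }
      r <- tryCatch({
        aln <- .codon_align_fast(sa, sb)
        if (is.null(aln)) {
          aln <- align_pair(translate_cds(.strip_terminal_stop(sa)),
                            translate_cds(.strip_terminal_stop(sb)), sa, sb)
        }
        ng86(aln, min_codons = min_codons)
      }, error = function(e) NULL)
      if (is.null(r)) {
        skipped <- skipped + 1L
        next
      }
      r <- cbind(
        data.frame(block_id = blk$block_id, gene_a = ga, gene_b = gb,
                   stringsAsFactors = FALSE),
        r
      )
      rows[[length(rows) + 1L]] <- r
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block_id = character(0), gene_a = character(0),
               gene_b = character(0))
  med <- NULL
  if (nrow(records) > 0) {
    dt <- data.table::as.data.table(records)
    Ks <- valid <- block_id <- NULL # NSE notes
    med <- as.data.frame(dt[, list(
      n_valid = sum(valid & !is.na(Ks)),
      median_ks = stats::median(Ks[valid & !is.na(Ks)])
    ), by = block_id])
  } else {
    med <- data.frame(block_id = character(0), n_valid = integer(0),
                      median_ks = numeric(0))
  }
  list(records = records, block_median_ks = med, n_skipped = skipped)
}
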