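# Codon bookkeeping for the NG86 counting method.
#
# All tables are built once per session from the standard genetic code and
# cached in an internal environment: per-codon synonymous site fractions
# (changes to stop codons excluded from both numerator and denominator) and
# 64x64 matrices of pathway-averaged synonymous/nonsynonymous differences.

.wgdclock_cache <- new.env(parent = emptyenv())

NUC <- c("T", "C", "A", "G")

#' All 64 codons in TCAG order
#' @return character vector of codons
#' @keywords internal
all_codons <- function() {
  as.vector(outer(outer(NUC, NUC, paste0), NUC, paste0))
}

#' Translate a codon with the standard genetic code
#' @param codon three-letter nucleotide string (T/C/A/G)
#' @return single amino-acid letter, `*` for stop
#' @keywords internal
codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

.codon_neighbours <- function(codon) {
  # the 9 single-nucleotide mutants of a codon
  out <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(NUC, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      out <- c(out, mut)
    }
  }
  out
}

# Per-codon synonymous site count: at each position, the fraction of
# non-stop single-nucleotide changes that are synonymous; each position
# contributes one site, so syn + nonsyn sites = 3 per codon.
.build_site_counts <- function() {
  codons <- all_codons()
  gc <- Biostrings::GENETIC_CODE
  s <- numeric(64)
  names(s) <- codons
  for (cd in codons) {
    if (gc[cd] == "*") {
      s[cd] <- NA_real_
      next
    }
    tot <- 0
    for (pos in 1:3) {
      nsyn <- 0L
      nvalid <- 0L
      for (nt in setdiff(NUC, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- nt
        if (gc[mut] == "*") next
        nvalid <- nvalid + 1L
        if (gc[mut] == gc[cd]) nsyn <- nsyn + 1L
      }
      if (nvalid > 0L) tot <- tot + nsyn / nvalid
    }
    s[cd] <- tot
  }
  s
}

# Pathway-averaged synonymous / nonsynonymous difference counts for every
# codon pair.  Minimal mutational pathways (orderings of the differing
# positions) are weighted equally; pathways passing through a stop codon are
# excluded; if every pathway is blocked by stops, all pathways are used.
.build_diff_tables <- function() {
  codons <- all_codons()
  gc <- Biostrings::GENETIC_CODE
  sd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  for (c1 in codons) {
    if (gc[c1] == "*") next
    for (c2 in codons) {
      if (gc[c2] == "*") next
      pos_diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      k <- length(pos_diff)
      if (k == 0L) next
      perms <- switch(k, list(1L), perms2, perms3)
      path_syn <- numeric(0)
      path_non <- numeric(0)
      path_ok <- logical(0)
      for (pm in perms) {
        cur <- c1
        nsyn <- 0
        nnon <- 0
        ok <- TRUE
        for (step in pm) {
          pos <- pos_diff[step]
          nxt <- cur
          substr(nxt, pos, pos) <- substr(c2, pos, pos)
          if (gc[nxt] == "*") ok <- FALSE
          if (gc[nxt] == gc[cur]) nsyn <- nsyn + 1 else nnon <- nnon + 1
          cur <- nxt
        }
        path_syn <- c(path_syn, nsyn)
        path_non <- c(path_non, nnon)
        path_ok <- c(path_ok, ok)
      }
      use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
      sd_mat[c1, c2] <- mean(path_syn[use])
      nd_mat[c1, c2] <- mean(path_non[use])
    }
  }
  list(sd = sd_mat, nd = nd_mat)
}

#' NG86 lookup tables (built lazily, cached)
#' @return list with `sites` (named numeric, synonymous sites per codon),
#'   `sd` and `nd` (64x64 pathway-averaged difference matrices)
#' @keywords internal
ng86_tables <- function() {
  if (is.null(.wgdclock_cache$ng86)) {
    diffs <- .build_diff_tables()
    .wgdclock_cache$ng86 <- list(
      sites = .build_site_counts(),
      sd = diffs$sd,
      nd = diffs$nd
    )
  }
  .wgdclock_cache$ng86
}

#' Split a CDS string into codons
#' @param cds nucleotide string, length divisible by 3
#' @return character vector of codons (uppercased, U -> T)
#' @keywords internal
split_codons <- function(cds) {
  cds <- chartr("u", "T", toupper(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3: ", n)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a CDS to protein
#' @param cds nucleotide string
#' @param drop_terminal_stop drop a trailing `*` if present
#' @return amino-acid string
#' @keywords internal
translate_cds <- function(cds, drop_terminal_stop = TRUE) {
  aa <- paste0(Biostrings::GENETIC_CODE[split_codons(cds)], collapse = "")
  if (drop_terminal_stop) aa <- sub("\\*$", "", aa)
  aa
}
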