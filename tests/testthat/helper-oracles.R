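# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

GC_TABLE <- Biostrings::GENETIC_CODE

# --- NG86 oracle: direct enumeration, no lookup tables ----------------------

# synonymous site count of one codon: per position, fraction of non-stop
# single-nucleotide changes that are synonymous
oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (nt in nts) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (GC_TABLE[[mut]] == "*") next
      valid <- valid + 1
      if (GC_TABLE[[mut]] == GC_TABLE[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# all orderings of a vector, by recursion
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# pathway-averaged (syn, nonsyn) differences between two codons; pathways
# through stop codons excluded, all pathways used if every one is blocked
oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, non = 0))
  paths <- oracle_perms(pos)
  res <- lapply(paths, function(ord) {
    cur <- c1
    syn <- 0
    non <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GC_TABLE[[nxt]] == "*") blocked <- TRUE
      if (GC_TABLE[[nxt]] == GC_TABLE[[cur]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    list(syn = syn, non = non, blocked = blocked)
  })
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  c(
    syn = mean(vapply(res[ok], `[[`, numeric(1), "syn")),
    non = mean(vapply(res[ok], `[[`, numeric(1), "non"))
  )
}

# full NG86 counts for two aligned codon vectors (no gaps/ambiguity handling:
# callers supply clean columns)
oracle_ng86_counts <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  d <- mapply(function(a, b) oracle_codon_diffs(a, b), codons_a, codons_b)
  list(S = S, N = N, Sd = sum(d["syn", ]), Nd = sum(d["non", ]))
}

# random sense-codon sampler
oracle_random_codons <- function(n) {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  sample(sense, n, replace = TRUE)
}

# --- collinear chain oracle: exhaustive subset enumeration ------------------

# best chain score over all subsets of <= 12 hits for one sequence pair;
# a subset is a valid chain if, sorted by rank_a, rank_a is strictly
# increasing with gaps <= max_gap and rank_b strictly monotone with a single
# sign and gaps <= max_gap; score = sum(hit scores) -
# gap_penalty * sum(d_a + |d_b| - 2) over consecutive steps
oracle_best_chain <- function(hits, max_gap, gap_penalty) {
  n <- nrow(hits)
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    sub <- hits[idx, , drop = FALSE]
    sub <- sub[order(sub$rank_a), , drop = FALSE]
    m <- nrow(sub)
    score <- sum(sub$score)
    valid_same <- TRUE
    valid_inv <- TRUE
    pen_same <- 0
    pen_inv <- 0
    if (m > 1) {
      for (i in 2:m) {
        da <- sub$rank_a[i] - sub$rank_a[i - 1]
        db <- sub$rank_b[i] - sub$rank_b[i - 1]
        if (!(da > 0 && da <= max_gap)) {
          valid_same <- FALSE
          valid_inv <- FALSE
          break
        }
        if (db > 0 && db <= max_gap) {
          valid_inv <- FALSE
          pen_same <- pen_same + gap_penalty * (da + db - 2)
        } else if (-db > 0 && -db <= max_gap) {
          valid_same <- FALSE
          pen_inv <- pen_inv + gap_penalty * (da - db - 2)
        } else {
          valid_same <- FALSE
          valid_inv <- FALSE
          break
        }
      }
    }
    if (valid_same) best <- max(best, score - pen_same)
    if (valid_inv) best <- max(best, score - pen_inv)
  }
  best
}

# --- N50 oracle -------------------------------------------------------------

oracle_n50 <- function(lens) {
  srt <- sort(lens, decreasing = TRUE)
  tot <- sum(lens)
  run <- 0
  for (i in seq_along(srt)) {
    run <- run + srt[i]
    if (run >= tot / 2) return(list(N50 = unname(srt[i]), L50 = i))
  }
}
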