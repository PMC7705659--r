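# Post-WGD subgenome behaviour: per-block gene retention against a reference
# genome, and expression-dominance testing of duplicate (homoeolog) pairs.

#' Subgenome gene-retention rates and bias test
#'
#' For each genomic block, the retention rate of subgenome X is
#' `|retained_X| / |ref genes in block|`. Retention bias is tested per block
#' by a two-sided exact binomial test on the genes retained in exactly one
#' subgenome (p = 0.5 under no bias), a pooled genome-wide test, and BH
#' correction across blocks.
#'
#' @param assignments data.frame `block_id`, `ref_gene`, `status` with
#'   status in `A`, `B`, `both`, `lost` (retention of each reference gene in
#'   the two subgenomes)
#' @param alpha significance level for the bias verdict (default 0.05)
#' @return list: `blocks` (data.frame `block_id`, `n_ref`, `rate_A`,
#'   `rate_B`, `n_only_A`, `n_only_B`, `p_value`, `q_value`, `biased`),
#'   `genome_wide` (rates + pooled binomial p)
#' @export
retention_rates <- function(assignments, alpha = 0.05) {
  stopifnot(all(c("block_id", "ref_gene", "status") %in% names(assignments)))
  bad <- !(assignments$status %in% c("A", "B", "both", "lost"))
  if (any(bad)) stop("unknown status values: ",
                     paste(unique(assignments$status[bad]), collapse = ", "))
  rows <- list()
  for (b in unique(assignments$block_id)) {
    sub <- assignments[assignments$block_id == b, , drop = FALSE]
    n_ref <- nrow(sub)
    if (n_ref == 0) {
      warning("block ", b, " has an empty reference set; skipped")
      next
    }
    n_a <- sum(sub$status %in% c("A", "both"))
    n_b <- sum(sub$status %in% c("B", "both"))
    only_a <- sum(sub$status == "A")
    only_b <- sum(sub$status == "B")
    p <- if (only_a + only_b > 0) {
      stats::binom.test(only_a, only_a + only_b, p = 0.5,
                        alternative = "two.sided")$p.value
    } else {
      1
    }
    rows[[length(rows) + 1L]] <- data.frame(
      block_id = b, n_ref = n_ref,
      rate_A = n_a / n_ref, rate_B = n_b / n_ref,
      n_only_A = only_a, n_only_B = only_b, p_value = p,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no usable blocks")
  blocks <- do.call(rbind, rows)
  blocks$q_value <- stats::p.adjust(blocks$p_value, method = "BH")
  blocks$biased <- blocks$q_value < alpha
  tot_a <- sum(blocks$n_only_A)
  tot_b <- sum(blocks$n_only_B)
  pooled_p <- if (tot_a + tot_b > 0) {
    stats::binom.test(tot_a, tot_a + tot_b, p = 0.5)$p.value
  } else {
    1
  }
  n_ref_all <- sum(blocks$n_ref)
  list(
    blocks = blocks,
    genome_wide = list(
      rate_A = sum(blocks$rate_A * blocks$n_ref) / n_ref_all,
      rate_B = sum(blocks$rate_B * blocks$n_ref) / n_ref_all,
      n_only_A = tot_a, n_only_B = tot_b, p_value = pooled_p
    )
  )
}

#' Expression-dominance test between subgenomes
#'
#' Per duplicate pair, the expression ratio `log2((expr_A + c)/(expr_B + c))`
#' is averaged over shared samples; per block, a two-sided Wilcoxon
#' signed-rank test of the ratios against 0 is BH-corrected across blocks. A
#' block is called dominant only when the adjusted p-value is below `alpha`
#' AND the median ratio magnitude reaches `effect_floor`; blocks with fewer
#' than `min_pairs` pairs are flagged underpowered and forced to "none".
#'
#' @param pairs data.frame `block_id`, `gene_a`, `gene_b` (A/B homoeologs)
#' @param expr numeric matrix, genes x samples (non-negative)
#' @param alpha significance level (default 0.05)
#' @param effect_floor minimum |median log2 ratio| to call dominance
#'   (default 1.0)
#' @param pseudocount added before the ratio (default 1)
#' @param min_pairs minimum pairs per block for a verdict (default 5)
#' @return data.frame `block_id`, `n_pairs`, `median_log2_ratio`, `p_value`,
#'   `q_value`, `verdict` (A-dominant/B-dominant/none), `flags`
#' @export
expression_dominance <- function(pairs, expr, alpha = 0.05,
                                 effect_floor = 1.0, pseudocount = 1,
                                 min_pairs = 5) {
  stopifnot(all(c("block_id", "gene_a", "gene_b") %in% names(pairs)))
  if (any(expr < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  ratio <- vapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]
    gb <- pairs$gene_b[i]
    if (!(ga %in% rownames(expr)) || !(gb %in% rownames(expr))) {
      return(NA_real_)
    }
    ea <- expr[ga, ]
    eb <- expr[gb, ]
    shared <- !is.na(ea) & !is.na(eb)
    if (!any(shared)) return(NA_real_)
    mean(log2((ea[shared] + pseudocount) / (eb[shared] + pseudocount)))
  }, numeric(1))
  rows <- list()
  for (b in unique(pairs$block_id)) {
    rr <- ratio[pairs$block_id == b]
    rr <- rr[!is.na(rr)]
    n <- length(rr)
    flags <- character(0)
    p <- if (n > 0 && any(rr != 0)) {
      suppressWarnings(stats::wilcox.test(rr, mu = 0)$p.value)
    } else {
      1
    }
    if (n < min_pairs) flags <- c(flags, "underpowered")
    rows[[length(rows) + 1L]] <- data.frame(
      block_id = b, n_pairs = n, median_log2_ratio = stats::median(rr),
      p_value = p, flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$verdict <- ifelse(
    out$q_value < alpha & abs(out$median_log2_ratio) >= effect_floor &
      out$n_pairs >= min_pairs,
    ifelse(out$median_log2_ratio > 0, "A-dominant", "B-dominant"),
    "none"
  )
  out[, c("block_id", "n_pairs", "median_log2_ratio", "p_value", "q_value",
          "verdict", "flags")]
}
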