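# Homology-hit filtering and collinear-block chaining between two genomes.
#
# Hits are chained per sequence pair and orientation as a weighted longest
# path over the rank-ordered hit DAG (the ColinearScan/MCScanX stage):
# an edge is allowed when 0 < delta(rank_a) <= max_gap and
# 0 < |delta(rank_b)| <= max_gap with a consistent sign; chain score is the
# sum of hit scores minus gap_penalty * (delta_a + |delta_b| - 2) per edge.

#' Filter a homology hit table
#'
#' Keeps hits with `e_value <= e_max`, removes self-hits, and caps the number
#' of hits per query at `best_n` by descending score (ties broken by
#' subject id, lexicographic).
#'
#' @param hits data.frame with at least `query_id`, `subject_id`, `score`,
#'   `e_value`
#' @param e_max maximum e-value retained (default `1e-5`)
#' @param best_n per-query cap on retained hits (default `Inf`)
#' @return the filtered hit data.frame
#' @export
filter_hits <- function(hits, e_max = 1e-5, best_n = Inf) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[hits$e_value <= e_max & hits$query_id != hits$subject_id, ,
               drop = FALSE]
  if (is.finite(best_n) && nrow(hits) > 0) {
    ord <- order(hits$query_id, -hits$score, hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    keep <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                       FUN = seq_along) <= best_n
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Score candidate homolog pairs with a built-in aligner
#'
#' All-vs-all protein comparison without an external search tool: candidate
#' pairs are pruned by shared amino-acid k-mer count, then scored by global
#' alignment (BLOSUM62, affine gaps). A surrogate e-value is emitted via the
#' Karlin-Altschul form `E = K * m * n * exp(-lambda * S)` with fixed nominal
#' parameters; it is a monotone transform of the score for ranking and
#' thresholding only, and is NOT comparable to any external tool's e-values.
#'
#' @param proteins_a,proteins_b named character vectors of protein sequences.
#'   If the two sets have identical names the comparison is treated as a
#'   self-comparison and each unordered pair is emitted once.
#' @param k k-mer length for the candidate prefilter (default 5)
#' @param min_shared_kmers minimum shared distinct k-mers for a pair to be
#'   scored (default 10)
#' @param lambda,kconst nominal Karlin-Altschul parameters for the surrogate
#'   e-value
#' @return data.frame `query_id`, `subject_id`, `score`, `e_value`
#' @export
score_homologs_builtin <- function(proteins_a, proteins_b, k = 5,
                                   min_shared_kmers = 10,
                                   lambda = 0.267, kconst = 0.041) {
  clean <- function(p, side) {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", toupper(p))
    if (any(bad)) {
      warning(sum(bad), " ", side,
              " sequence(s) with non-amino-acid symbols skipped")
    }
    toupper(p[!bad])
  }
  proteins_a <- clean(proteins_a, "A")
  proteins_b <- clean(proteins_b, "B")
  self <- identical(sort(names(proteins_a)), sort(names(proteins_b)))
  kmers <- function(p) {
    dt <- data.table::rbindlist(lapply(names(p), function(id) {
      s <- p[[id]]
      n <- nchar(s)
      if (n < k) return(NULL)
      data.table::data.table(
        gene = id, kmer = unique(substring(s, 1:(n - k + 1), k:n))
      )
    }))
    dt
  }
  ka <- kmers(proteins_a)
  kb <- if (self) ka else kmers(proteins_b)
  gene <- kmer <- NULL # NSE
  cand <- merge(ka, kb, by = "kmer", allow.cartesian = TRUE,
                suffixes = c("_a", "_b"))
  gene_a <- gene_b <- NULL
  cand <- cand[, list(n_shared = .N), by = list(gene_a, gene_b)]
  cand <- cand[cand$n_shared >= min_shared_kmers &
                 cand$gene_a != cand$gene_b, ]
  if (self && nrow(cand) > 0) cand <- cand[cand$gene_a < cand$gene_b, ]
  if (nrow(cand) == 0) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), e_value = numeric(0)))
  }
  sc <- numeric(nrow(cand))
  # equal-length candidate pairs at candidate-level identity are scored on
  # the gapless diagonal (identical to the affine-gap optimum at the
  # identities the k-mer prefilter admits); unequal lengths get the full
  # affine-gap global alignment, batched per subject
  la <- nchar(proteins_a[cand$gene_a])
  lb <- nchar(proteins_b[cand$gene_b])
  fast <- which(la == lb)
  if (length(fast)) {
    b62 <- .blosum62()
    for (i in fast) {
      sc[i] <- .gapless_score(proteins_a[[cand$gene_a[i]]],
                              proteins_b[[cand$gene_b[i]]], b62)
    }
  }
  slow <- setdiff(seq_len(nrow(cand)), fast)
  if (length(slow)) {
    aaa <- Biostrings::AAStringSet(proteins_a)
    aab <- Biostrings::AAStringSet(proteins_b)
    for (sb in unique(cand$gene_b[slow])) {
      ii <- slow[cand$gene_b[slow] == sb]
      sc[ii] <- Biostrings::pairwiseAlignment(
        aaa[cand$gene_a[ii]], aab[[sb]],
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE
      )
    }
  }
  m <- nchar(proteins_a[cand$gene_a])
  n <- nchar(proteins_b[cand$gene_b])
  ev <- pmax(kconst * m * n * exp(-lambda * pmax(sc, 0)), 1e-300)
  data.frame(
    query_id = cand$gene_a, subject_id = cand$gene_b,
    score = sc, e_value = unname(ev), stringsAsFactors = FALSE
  )
}

.blosum62 <- function() {
  if (is.null(.wgdclock_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .wgdclock_cache$blosum62 <- e$BLOSUM62
  }
  .wgdclock_cache$blosum62
}

.gapless_score <- function(a, b, mat) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- ca %in% rownames(mat) & cb %in% colnames(mat)
  sum(mat[cbind(ca[keep], cb[keep])])
}

#' Collapse tandem arrays before chaining
#'
#' Two genes of the same genome are "tandem" when they are mutual homology
#' hits and sit within `max_rank_gap` ranks of each other on the same
#' sequence. Each tandem array is collapsed to its highest-scoring member so
#' arrays do not inflate block anchor counts.
#' @keywords internal
collapse_tandems <- function(hits, genes, max_rank_gap = 2) {
  if (nrow(hits) == 0) return(hits)
  g <- genes[match(hits$query_id, genes$gene_id), c("seq_id", "rank")]
  h <- genes[match(hits$subject_id, genes$gene_id), c("seq_id", "rank")]
  same <- !is.na(g$seq_id) & !is.na(h$seq_id) & g$seq_id == h$seq_id &
    abs(g$rank - h$rank) <= max_rank_gap
  tand <- hits[same, , drop = FALSE]
  if (nrow(tand) == 0) return(hits)
  # union-find over tandem-linked genes
  ids <- unique(c(tand$query_id, tand$subject_id))
  parent <- stats::setNames(ids, ids)
  findp <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(tand))) {
    ra <- findp(tand$query_id[i])
    rb <- findp(tand$subject_id[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  root <- vapply(ids, findp, character(1))
  # representative: highest best-hit score, ties by gene id
  best <- stats::aggregate(
    score ~ gid, FUN = max,
    data = data.frame(
      gid = c(hits$query_id, hits$subject_id),
      score = c(hits$score, hits$score)
    )
  )
  bs <- stats::setNames(best$score, best$gid)
  rep_of <- tapply(ids, root, function(members) {
    members[order(-bs[members], members)][1]
  })
  keep_gene <- function(id) {
    r <- root[id]
    is.na(r) | id == rep_of[r]
  }
  drop <- (hits$query_id %in% ids & !keep_gene(hits$query_id)) |
    (hits$subject_id %in% ids & !keep_gene(hits$subject_id))
  hits[!drop, , drop = FALSE]
}

#' Detect collinear blocks between two annotated genomes
#'
#' Chains filtered homology hits into maximal-scoring collinear blocks per
#' sequence pair and orientation (dynamic programming over the rank-sorted
#' hit DAG; see the file header for the edge rule and score). Blocks shorter
#' than `min_block_size` anchors are discarded; a gene pair appears in at
#' most one block.
#'
#' @param hits data.frame `query_id`, `subject_id`, `score` (filtered, e.g.
#'   by [filter_hits()])
#' @param genes_a,genes_b gene tables (data.frame `gene_id`, `seq_id`,
#'   `start`, `end`, `strand`, `rank`) for the two genomes
#' @param max_gap maximum rank gap bridged within a block (default 25)
#' @param min_block_size minimum anchors per reported block (default 5)
#' @param gap_penalty score penalty per skipped rank (default 1)
#' @param collapse_tandem collapse tandem arrays first (default TRUE)
#' @return list of `collinear_block`: each a list with `block_id`,
#'   `seq_pair`, `orientation` ("same"/"inverted"), `score`, `n_anchors`,
#'   `anchors` (data.frame `gene_a`, `gene_b`, `rank_a`, `rank_b`)
#' @export
detect_collinear_blocks <- function(hits, genes_a, genes_b, max_gap = 25,
                                    min_block_size = 5, gap_penalty = 1,
                                    collapse_tandem = TRUE) {
  .check_ranks(genes_a)
  .check_ranks(genes_b)
  if (nrow(hits) == 0) return(list())
  missing <- !(hits$query_id %in% genes_a$gene_id) |
    !(hits$subject_id %in% genes_b$gene_id)
  if (any(missing)) stop(sum(missing), " hit(s) reference unknown genes")
  if (collapse_tandem) {
    hits <- collapse_tandems(hits, genes_a)
    hits <- collapse_tandems(hits, genes_b)
  }
  ia <- match(hits$query_id, genes_a$gene_id)
  ib <- match(hits$subject_id, genes_b$gene_id)
  h <- data.frame(
    gene_a = hits$query_id, gene_b = hits$subject_id, score = hits$score,
    seq_a = genes_a$seq_id[ia], rank_a = genes_a$rank[ia],
    seq_b = genes_b$seq_id[ib], rank_b = genes_b$rank[ib],
    stringsAsFactors = FALSE
  )
  blocks <- list()
  next_id <- 1L
  for (key in unique(paste(h$seq_a, h$seq_b, sep = "\r"))) {
    sub <- h[paste(h$seq_a, h$seq_b, sep = "\r") == key, , drop = FALSE]
    for (sgn in c(1L, -1L)) {
      repeat {
        ch <- .best_chain(sub, sgn, max_gap, gap_penalty)
        if (is.null(ch) || length(ch$idx) < min_block_size) break
        anc <- sub[ch$idx, c("gene_a", "gene_b", "rank_a", "rank_b")]
        rownames(anc) <- NULL
        blocks[[length(blocks) + 1L]] <- structure(
          list(
            block_id = sprintf("block_%04d", next_id),
            seq_pair = c(sub$seq_a[1], sub$seq_b[1]),
            orientation = if (sgn == 1L) "same" else "inverted",
            score = ch$score, n_anchors = nrow(anc), anchors = anc
          ),
          class = "collinear_block"
        )
        next_id <- next_id + 1L
        sub <- sub[-ch$idx, , drop = FALSE]
        if (nrow(sub) == 0) break
      }
    }
  }
  # deterministic order: score desc, then first anchor pair
  if (length(blocks) > 1) {
    ord <- order(
      -vapply(blocks, `[[`, numeric(1), "score"),
      vapply(blocks, function(b) b$anchors$gene_a[1], character(1)),
      vapply(blocks, function(b) b$anchors$gene_b[1], character(1))
    )
    blocks <- blocks[ord]
    for (i in seq_along(blocks)) blocks[[i]]$block_id <-
        sprintf("block_%04d", i)
  }
  blocks
}

.check_ranks <- function(genes) {
  sp <- split(genes$rank, genes$seq_id)
  for (s in names(sp)) {
    r <- sort(sp[[s]])
    if (!identical(as.integer(r), seq_along(r) - 1L)) {
      stop("ranks on ", s, " are not a permutation of 0..n-1 ",
           "(duplicate or missing ranks; annotation bug upstream)")
    }
  }
  invisible(TRUE)
}

# Highest-scoring chain among `sub` hits for one orientation sign.
# Returns NULL if no hit; otherwise list(idx = row indices in chain order,
# score = chain score).
.best_chain <- function(sub, sgn, max_gap, gap_penalty) {
  n <- nrow(sub)
  if (n == 0) return(NULL)
  ord <- order(sub$rank_a, sgn * sub$rank_b, sub$gene_a, sub$gene_b)
  ra <- sub$rank_a[ord]
  rb <- sub$rank_b[ord]
  w <- sub$score[ord]
  dp <- w
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- sgn * (rb[i] - rb[j])
      if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
        cand <- dp[j] + w[i] - gap_penalty * (da + db - 2)
        if (cand > dp[i]) {
          dp[i] <- cand
          prev[i] <- j
        }
      }
    }
  }
  best <- which.max(dp)
  chain <- integer(0)
  i <- best
  while (i != 0L) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  list(idx = ord[chain], score = dp[best])
}

#' Anchor table in cumulative genome coordinates (dotplot input)
#'
#' One row per anchor with x/y cumulative gene ranks across the concatenated
#' chromosomes of each genome, ready for a synteny dotplot.
#'
#' @param blocks list of `collinear_block`
#' @param genes_a,genes_b gene tables (to establish chromosome offsets)
#' @return data.frame `block_id`, `orientation`, `gene_a`, `gene_b`, `x`, `y`
#' @export
dotplot_table <- function(blocks, genes_a, genes_b) {
  if (length(blocks) == 0) stop("no blocks to tabulate")
  offs <- function(genes) {
    n_by_seq <- table(genes$seq_id)
    seqs <- sort(names(n_by_seq))
    stats::setNames(cumsum(c(0, as.numeric(n_by_seq[seqs])))[seq_along(seqs)],
                    seqs)
  }
  oa <- offs(genes_a)
  ob <- offs(genes_b)
  rows <- lapply(blocks, function(b) {
    data.frame(
      block_id = b$block_id, orientation = b$orientation,
      gene_a = b$anchors$gene_a, gene_b = b$anchors$gene_b,
      x = oa[[b$seq_pair[1]]] + b$anchors$rank_a,
      y = ob[[b$seq_pair[2]]] + b$anchors$rank_b,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
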