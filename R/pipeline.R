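# End-to-end WGD dating pipeline over a (simulated or user-supplied) genome
# pair: homology search -> hit filtering -> collinear-block chaining ->
# NG86 Ks per anchor -> Ks distributions -> mixture peaks -> rate-corrected
# event dating.

#' Protein sequences for a gene table
#' @param genes gene data.frame with `gene_id` and `cds`
#' @return named character vector of proteins
#' @export
gene_proteins <- function(genes) {
  stats::setNames(vapply(genes$cds, translate_cds, character(1),
                         USE.NAMES = FALSE),
                  genes$gene_id)
}

#' Homology hits, blocks and Ks records for one genome comparison
#'
#' Runs the built-in homolog scorer, e-value filtering, tandem collapse +
#' chaining, and NG86 Ks on every anchor. `genes_a` and `genes_b` may be the
#' same table (self-comparison for paralog blocks).
#'
#' @param genes_a,genes_b gene data.frames (with `cds`)
#' @param e_max hit e-value cutoff (default 1e-5)
#' @param max_gap,min_block_size,gap_penalty chaining parameters
#' @param min_codons minimum ungapped codons for a valid Ks
#' @return list `hits`, `blocks`, `ks` (the [ks_for_blocks()] result)
#' @export
compare_genomes <- function(genes_a, genes_b, e_max = 1e-5, max_gap = 25,
                            min_block_size = 5, gap_penalty = 1,
                            min_codons = 30) {
  prot_a <- gene_proteins(genes_a)
  prot_b <- gene_proteins(genes_b)
  hits <- score_homologs_builtin(prot_a, prot_b)
  hits <- filter_hits(hits, e_max = e_max)
  blocks <- detect_collinear_blocks(hits, genes_a, genes_b,
                                    max_gap = max_gap,
                                    min_block_size = min_block_size,
                                    gap_penalty = gap_penalty)
  cds_a <- stats::setNames(genes_a$cds, genes_a$gene_id)
  cds_b <- stats::setNames(genes_b$cds, genes_b$gene_id)
  ks <- ks_for_blocks(blocks, cds_a, cds_b, min_codons = min_codons)
  list(hits = hits, blocks = blocks, ks = ks)
}

#' Full WGD dating pipeline on a simulated genome pair
#'
#' Simulates a genome pair, detects paralog blocks within each genome and
#' ortholog blocks between them, builds the three Ks distributions, fits
#' mixture peaks, and dates the WGD events with the evolutionary-rate
#' correction (the reference genome's paralog peak calibrates `W_L` for the
#' shared event).
#'
#' @param config a [sim_config()]
#' @param k_range mixture component counts tried (default 1:4)
#' @param lo,hi Ks filter bounds for distribution building
#' @param ... passed to [compare_genomes()]
#' @return list: `sim` (genomes + truth), `focal`, `reference`, `ortholog`
#'   (each a [compare_genomes()] result), `distributions`, `peaks`,
#'   `dating` (the [date_wgd_events()] result)
#' @export
run_wgd_pipeline <- function(config, k_range = 1:4, lo = 0.005, hi = 3.0,
                             ...) {
  sim <- simulate_genome_pair(config)
  focal <- compare_genomes(sim$genome_l, sim$genome_l, ...)
  reference <- compare_genomes(sim$genome_c, sim$genome_c, ...)
  ortholog <- compare_genomes(sim$genome_l, sim$genome_c, ...)
  dists <- list(
    paralog_L = build_distribution(focal$ks$records, lo, hi,
                                   source = "paralog_L"),
    paralog_C = build_distribution(reference$ks$records, lo, hi,
                                   source = "paralog_C"),
    ortholog_LC = build_distribution(ortholog$ks$records, lo, hi,
                                     source = "ortholog_LC")
  )
  peaks <- list(
    paralog_L = fit_peaks(dists$paralog_L, k_range = k_range,
                          seed = config$seed),
    paralog_C = fit_peaks(dists$paralog_C, k_range = k_range,
                          seed = config$seed),
    ortholog_LC = fit_peaks(dists$ortholog_LC, k_range = k_range,
                            seed = config$seed)
  )
  focal_peaks <- .label_focal_peaks(peaks$paralog_L)
  ref_peak <- .major_peak(peaks$paralog_C)
  orth_peak <- .ortholog_peak(peaks$ortholog_LC)
  dating <- date_wgd_events(
    focal_peaks, reference_shared_peak = ref_peak,
    shared_label = "shared", ortholog_peak = orth_peak,
    subst_rate = config$subst_rate
  )
  list(sim = sim, focal = focal, reference = reference, ortholog = ortholog,
       distributions = dists, peaks = peaks, dating = dating)
}

# two highest-density modes of the fitted mixture: the smaller-Ks mode is
# the (younger) lineage-specific event, the larger the shared event
.label_focal_peaks <- function(pm) {
  modes <- mixture_modes(pm)
  if (nrow(modes) < 2) {
    stop("focal paralog distribution is unimodal; ",
         "cannot separate the specific and shared events")
  }
  top <- modes[order(-modes$density)[1:2], ]
  top <- top[order(top$mode_ks), ]
  c(specific = top$mode_ks[1], shared = top$mode_ks[2])
}

.major_peak <- function(pm) {
  modes <- mixture_modes(pm)
  modes$mode_ks[which.max(modes$density)]
}

# the between-species distribution mixes true ortholog anchors (split-age
# divergence) with cross-subgenome anchors dated by the shared event; the
# divergence peak is the youngest substantial mode
.ortholog_peak <- function(pm, min_density_frac = 0.25) {
  modes <- mixture_modes(pm, min_density_frac = min_density_frac)
  min(modes$mode_ks)
}
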