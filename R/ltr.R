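# Molecular-clock dating of LTR retrotransposon insertions from the
# divergence of an element's paired 5'/3' LTRs: the two repeats are
# identical at insertion, so their corrected distance d gives the insertion
# time T = d / (2 * mu).

#' Divergence between the two LTRs of an element
#'
#' Computes the p-distance over ungapped aligned columns (global nucleotide
#' alignment is performed internally when the sequences differ in length)
#' and corrects it under the chosen model: JC69
#' `d = -(3/4) ln(1 - 4p/3)`, or K80 (default) using transition/transversion
#' proportions `d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)`.
#'
#' @param ltr5,ltr3 nucleotide strings (>= 100 nt)
#' @param model "K80" (default) or "JC69"
#' @param gap_flag_frac flag the estimate low-confidence when internal gaps
#'   exceed this fraction of the aligned length (default 0.2)
#' @return list: `p` (raw proportion), `d` (corrected distance, NA when
#'   saturated), `model`, `n_sites`, `flags` (character vector)
#' @export
ltr_divergence <- function(ltr5, ltr3, model = c("K80", "JC69"),
                           gap_flag_frac = 0.2) {
  model <- match.arg(model)
  ltr5 <- toupper(ltr5)
  ltr3 <- toupper(ltr3)
  if (nchar(ltr5) < 100 || nchar(ltr3) < 100) {
    stop("LTR sequences must be >= 100 nt")
  }
  flags <- character(0)
  if (nchar(ltr5) == nchar(ltr3)) {
    a <- strsplit(ltr5, "")[[1]]
    b <- strsplit(ltr3, "")[[1]]
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ltr5), Biostrings::DNAString(ltr3),
      type = "global", gapOpening = 10, gapExtension = 0.5
    )
    a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    gap_frac <- mean(a == "-" | b == "-")
    if (gap_frac > gap_flag_frac) flags <- c(flags, "low_confidence_gaps")
  }
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  if (n == 0) stop("no comparable ungapped columns")
  diff <- a != b
  p <- mean(diff)
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  d <- if (model == "JC69") {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) NA_real_ else -0.75 * log(arg)
  } else {
    P <- mean(diff & is_transition(a, b))
    Q <- p - P
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    if (a1 <= 0 || a2 <= 0) NA_real_ else -0.5 * log(a1) - 0.25 * log(a2)
  }
  if (is.na(d)) flags <- c(flags, "saturated")
  list(p = p, d = d, model = model, n_sites = n, flags = flags)
}

#' Insertion time from LTR divergence
#'
#' `T = d / (2 * mu)` in years: each LTR accumulates substitutions
#' independently since insertion, so the pair diverges at twice the rate.
#'
#' @param d corrected divergence (substitutions/site, >= 0)
#' @param mu substitution rate /site/year (default 7e-9)
#' @return insertion time in years
#' @examples
#' insertion_time(0.014) # 1e6 years
#' @export
insertion_time <- function(d, mu = 7e-9) {
  stopifnot(all(d >= 0, na.rm = TRUE), mu > 0)
  d / (2 * mu)
}

#' Date a table of LTR elements
#'
#' @param elements data.frame `element_id`, `ltr5`, `ltr3` (and optionally
#'   `species`)
#' @param mu substitution rate /site/year
#' @param model divergence model, "K80" or "JC69"
#' @return data.frame `element_id`, `p`, `d`, `model`, `age_years`, `flags`
#'   (+ `species` if present)
#' @export
date_ltr_elements <- function(elements, mu = 7e-9, model = "K80") {
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    dv <- ltr_divergence(elements$ltr5[i], elements$ltr3[i], model = model)
    data.frame(
      element_id = elements$element_id[i], p = dv$p, d = dv$d,
      model = dv$model,
      age_years = if (is.na(dv$d)) NA_real_ else insertion_time(dv$d, mu),
      flags = paste(dv$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(elements$species)) out$species <- elements$species
  out
}

#' Insertion-age histogram per species
#'
#' Bins dated elements into half-open age bins `[k*w, (k+1)*w)` in million
#' years, one row per species and bin (the insertion-time profile figure's
#' underlying table).
#'
#' @param dated data.frame with `age_years` and optionally `species`
#' @param bin_width_myr bin width in million years (default 0.5)
#' @return data.frame `species`, `bin_lo_myr`, `bin_hi_myr`, `count`
#' @export
age_profile <- function(dated, bin_width_myr = 0.5) {
  dated <- dated[!is.na(dated$age_years), , drop = FALSE]
  if (nrow(dated) == 0) stop("no dated elements")
  sp <- if (is.null(dated$species)) rep("all", nrow(dated)) else
    dated$species
  age_myr <- dated$age_years / 1e6
  bin <- floor(age_myr / bin_width_myr)
  tab <- as.data.frame(table(species = sp, bin = bin),
                       stringsAsFactors = FALSE)
  data.frame(
    species = tab$species,
    bin_lo_myr = as.numeric(tab$bin) * bin_width_myr,
    bin_hi_myr = (as.numeric(tab$bin) + 1) * bin_width_myr,
    count = tab$Freq,
    stringsAsFactors = FALSE
  )
}
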