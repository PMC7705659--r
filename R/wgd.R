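# Ks distributions, mixture-model peak detection, evolutionary-rate
# correction and conversion of corrected peaks to ages.
#
# The correction: if a duplication event shared by the focal lineage L and a
# reference lineage C produces Ks peaks k_L and k_C, the relative rate of L
# is r = (k_L - k_C)/k_C and the correction coefficient W_L = 1/(1 + r);
# every focal-lineage peak (including the between-species ortholog peak) is
# rescaled by W_L before conversion to time via T = Ks / (2 * subst_rate).

#' Build a filtered Ks distribution
#'
#' Keeps valid, finite Ks values within `[lo, hi]`; reports exclusion counts.
#'
#' @param ks_records data.frame with `Ks` and `valid` columns (as produced by
#'   [ks_for_blocks()]), or a numeric vector of Ks values
#' @param lo,hi inclusion bounds (defaults 0.005 and 3.0; the lower bound
#'   drops allelic/zero-divergence pairs, the upper saturated estimates)
#' @param source label for the distribution (e.g. "paralog_L")
#' @return `ks_distribution`: list with `values`, `source`, `filter_bounds`,
#'   `n_excluded` (named: invalid, below, above)
#' @export
build_distribution <- function(ks_records, lo = 0.005, hi = 3.0,
                               source = "paralog") {
  if (is.data.frame(ks_records)) {
    valid <- ks_records$valid & !is.na(ks_records$Ks) &
      is.finite(ks_records$Ks)
    v <- ks_records$Ks[valid]
    n_invalid <- sum(!valid)
  } else {
    v <- ks_records[!is.na(ks_records) & is.finite(ks_records)]
    n_invalid <- length(ks_records) - length(v)
  }
  below <- v < lo
  above <- v > hi
  out <- structure(
    list(
      values = v[!below & !above], source = source,
      filter_bounds = c(lo = lo, hi = hi),
      n_excluded = c(invalid = n_invalid, below = sum(below),
                     above = sum(above))
    ),
    class = "ks_distribution"
  )
  if (length(out$values) < 50) {
    warning("only ", length(out$values),
            " Ks values survive filtering; peak fitting is unreliable")
  }
  out
}

#' Fit mixture components to a Ks distribution
#'
#' Fits Gaussian mixtures to log(Ks) (i.e. lognormal components on the Ks
#' scale, appropriate for a positive, right-skewed quantity) by EM for each
#' component count in `k_range`; the count is chosen by BIC. Peak locations
#' are the component medians back-transformed to the Ks scale. A kernel
#' density local-maxima cross-check is available via `method = "kde"`.
#'
#' @param dist a `ks_distribution` (or numeric vector of Ks values)
#' @param k_range candidate component counts (default 1:4)
#' @param seed integer seed (the EM initialisation is deterministic, but the
#'   seed is fixed for reproducibility of any stochastic restart)
#' @param method "gmm" (default) or "kde"
#' @return `peak_model`: list with `components` (data.frame `weight`,
#'   `mean_log`, `sd_log`, `peak_ks`), `n_components`, `model_score` (BIC),
#'   `peak_locations` (Ks scale, ascending), `method`
#' @export
fit_peaks <- function(dist, k_range = 1:4, seed = 1, method = c("gmm", "kde")) {
  method <- match.arg(method)
  v <- if (inherits(dist, "ks_distribution")) dist$values else
    as.numeric(dist)
  v <- v[v > 0 & is.finite(v)]
  if (length(v) < 50) stop("need >= 50 positive Ks values to fit peaks")
  if (method == "kde") {
    d <- stats::density(log(v), bw = "SJ")
    ymax <- which(diff(sign(diff(d$y))) == -2) + 1L
    pk <- exp(d$x[ymax])
    return(structure(
      list(components = NULL, n_components = length(pk),
           model_score = NA_real_, peak_locations = sort(pk),
           method = "kde"),
      class = "peak_model"
    ))
  }
  .with_seed(seed, {
    fit <- mclust::Mclust(log(v), G = k_range, modelNames = "V",
                          verbose = FALSE)
    if (is.null(fit)) stop("mixture fitting failed to converge for all k")
    mu <- as.numeric(fit$parameters$mean)
    sdv <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sdv) == 1L) sdv <- rep(sdv, length(mu))
    w <- as.numeric(fit$parameters$pro)
    ord <- order(mu)
    comp <- data.frame(
      weight = w[ord], mean_log = mu[ord], sd_log = sdv[ord],
      peak_ks = exp(mu[ord])
    )
    structure(
      list(components = comp, n_components = nrow(comp),
           model_score = as.numeric(fit$bic),
           peak_locations = comp$peak_ks, method = "gmm",
           posterior = fit$z[, ord, drop = FALSE], values = v),
      class = "peak_model"
    )
  })
}

#' Modes of a fitted Ks mixture
#'
#' BIC occasionally represents one skewed peak with two overlapping
#' components; the biologically meaningful peak locations are therefore the
#' local maxima of the fitted mixture density, not the component means.
#' Density is evaluated on the log-Ks scale and modes are reported on the Ks
#' scale.
#'
#' @param pm a `peak_model` from [fit_peaks()] (gmm method)
#' @param min_density_frac discard modes whose density is below this
#'   fraction of the highest mode (default 0.1)
#' @param n_grid grid resolution (default 2048)
#' @return data.frame `mode_ks`, `density`, ordered by ascending `mode_ks`
#' @export
mixture_modes <- function(pm, min_density_frac = 0.1, n_grid = 2048) {
  comp <- pm$components
  if (is.null(comp)) stop("mixture_modes needs a gmm peak_model")
  lo <- min(comp$mean_log - 4 * comp$sd_log)
  hi <- max(comp$mean_log + 4 * comp$sd_log)
  x <- seq(lo, hi, length.out = n_grid)
  dens <- rowSums(vapply(seq_len(nrow(comp)), function(i) {
    comp$weight[i] * stats::dnorm(x, comp$mean_log[i], comp$sd_log[i])
  }, numeric(length(x))))
  imax <- which(diff(sign(diff(dens))) == -2) + 1L
  if (length(imax) == 0) imax <- which.max(dens)
  keep <- dens[imax] >= min_density_frac * max(dens[imax])
  imax <- imax[keep]
  data.frame(mode_ks = exp(x[imax]), density = dens[imax])
}

#' Relative evolutionary rate from a shared event's peaks
#'
#' `r = (k_L - k_C) / k_C`: the rate excess of the focal lineage L over the
#' reference lineage C, measured at a duplication event both lineages share.
#' Negative when the focal lineage is slower.
#'
#' @param k_c reference-lineage Ks peak of the shared event (> 0)
#' @param k_l focal-lineage Ks peak of the same event
#' @return r (dimensionless)
#' @export
relative_rate <- function(k_c, k_l) {
  if (k_c <= 0) stop("reference peak k_c must be > 0")
  (k_l - k_c) / k_c
}

#' Rate-correct a Ks value
#'
#' Returns `w_l * k` with `w_l = 1/(1 + r)`. Applied to the focal shared
#' peak itself this returns the reference peak exactly (algebraic identity).
#'
#' @param k Ks value (focal-lineage scale)
#' @param w_l correction coefficient (> 0)
#' @return corrected Ks
#' @export
correct_ks <- function(k, w_l) {
  if (any(w_l <= 0)) stop("w_l must be > 0")
  w_l * k
}

#' Convert a Ks value to a divergence time
#'
#' `T = Ks / (2 * subst_rate)`, reported in million years. Values are kept
#' unrounded internally; round only at presentation (the conventional print
#' shows 2 decimals).
#'
#' @param ks synonymous distance (>= 0)
#' @param subst_rate neutral substitution rate /site/year (default 8.22e-9)
#' @return age in Mya (numeric, unrounded)
#' @examples
#' round(ks_to_time(0.378), 2) # 22.99
#' round(ks_to_time(0.855), 2) # 52.01
#' @export
ks_to_time <- function(ks, subst_rate = 8.22e-9) {
  stopifnot(all(ks >= 0), subst_rate > 0)
  ks / (2 * subst_rate) / 1e6
}

#' Date WGD events with evolutionary-rate correction
#'
#' Computes `r` and `W_L` from the declared pairing of one focal peak with
#' one reference peak for the shared event, applies `W_L` to every focal
#' peak (and to the ortholog peak when given), and converts corrected peaks
#' to ages. Full provenance of the correction is carried on every row.
#'
#' @param focal_peaks named numeric: Ks peaks of the focal lineage's paralog
#'   distribution (e.g. `c(specific = 0.58, shared = 1.29)`)
#' @param reference_shared_peak the reference lineage's peak for the shared
#'   event (k_C)
#' @param shared_label name in `focal_peaks` that is the same shared event
#'   (pairs k_L with k_C); mandatory — without it the correction is undefined
#' @param ortholog_peak optional between-species Ks peak, corrected with the
#'   same `W_L` and reported as event "divergence"
#' @param subst_rate neutral substitution rate /site/year
#' @return list with `events` (data.frame `label`, `raw_peak`,
#'   `corrected_peak`, `age_mya`, `age_mya_uncorrected`) and `correction`
#'   (list `k_c`, `k_l`, `r`, `w_l`, `shared_label`)
#' @export
date_wgd_events <- function(focal_peaks, reference_shared_peak, shared_label,
                            ortholog_peak = NULL, subst_rate = 8.22e-9) {
  if (missing(shared_label) || is.null(shared_label) ||
      !(shared_label %in% names(focal_peaks))) {
    stop("a shared-event pairing must be declared: 'shared_label' must name ",
         "one entry of focal_peaks (correction undefined otherwise)")
  }
  k_l <- unname(focal_peaks[[shared_label]])
  k_c <- reference_shared_peak
  r <- relative_rate(k_c, k_l)
  w_l <- 1 / (1 + r)
  labels <- names(focal_peaks)
  raw <- unname(focal_peaks)
  corrected <- correct_ks(raw, w_l)
  if (!is.null(ortholog_peak)) {
    labels <- c(labels, "divergence")
    raw <- c(raw, ortholog_peak)
    corrected <- c(corrected, correct_ks(ortholog_peak, w_l))
  }
  events <- data.frame(
    label = labels, raw_peak = raw, corrected_peak = corrected,
    age_mya = ks_to_time(corrected, subst_rate),
    age_mya_uncorrected = ks_to_time(raw, subst_rate),
    stringsAsFactors = FALSE
  )
  list(
    events = events,
    correction = list(k_c = k_c, k_l = k_l, r = r, w_l = w_l,
                      shared_label = shared_label,
                      formula = "r=(k_L-k_C)/k_C; W_L=1/(1+r); T=Ks/(2*rate)")
  )
}
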