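# Monte-Carlo confidence bands for the windowed delta SNP index under the
# no-linkage null.
#
# Null model per replicate: one bulk allele frequency is drawn per pool for
# the whole window (sites within a 25-kb window are effectively fully
# linked: 25 kb is far below 1 cM, and independent per-site draws would
# understate the null variance of the window mean). The frequency is
# binomial over the bulk's 2N chromosomes at expectation 1/2 — the
# unlinked-locus expectation for either bulk of a selfed-heterozygote F2 —
# and read counts are then binomial at the observed per-site depths.

#' Null-band settings
#'
#' @param alpha Significance level (default 0.01, the single-window peak
#'   criterion).
#' @param n_sims Monte-Carlo replicates per window (default 10,000;
#'   minimum 100).
#' @param sidedness `"two_sided_band"` (default) flags windows outside the
#'   central 1-alpha band; `"upper_only"` flags only windows above the
#'   1-alpha quantile (peak calls).
#' @param seed Optional integer seed making band computation reproducible.
#' @return A `band_spec` list.
#' @export
band_spec <- function(alpha = 0.01, n_sims = 10000,
                      sidedness = c("two_sided_band", "upper_only"),
                      seed = NULL) {
  sidedness <- match.arg(sidedness)
  stopifnot(alpha > 0, alpha < 1, n_sims >= 100)
  structure(list(alpha = alpha, n_sims = as.integer(n_sims),
                 sidedness = sidedness, seed = seed),
            class = "band_spec")
}

#' Simulate the null distribution of one window's mean delta SNP index
#'
#' Each replicate draws one null bulk frequency per pool
#' (`X / (2N)` with `X ~ Binomial(2N, 1/2)`), then per-site alt-read counts
#' binomial at the observed depths, and returns the window mean of the
#' per-site delta SNP indices.
#'
#' @param depths_mut,depths_wt Observed per-site depths in the window
#'   (equal length, all positive).
#' @param design A [cross_design()] supplying the bulk sizes.
#' @param n_sims Number of replicates.
#' @param seed Optional seed.
#' @return Numeric vector of `n_sims` simulated window means.
#' @export
simulate_null_window <- function(depths_mut, depths_wt, design,
                                 n_sims = 10000, seed = NULL) {
  stopifnot(length(depths_mut) >= 1,
            length(depths_mut) == length(depths_wt),
            all(depths_mut > 0), all(depths_wt > 0))
  if (!is.null(seed)) set.seed(seed)
  n_mut <- design$mut_bulk_size
  n_wt <- design$wt_bulk_size
  s <- length(depths_mut)
  f_mut <- stats::rbinom(n_sims, 2L * n_mut, 0.5) / (2 * n_mut)
  f_wt <- stats::rbinom(n_sims, 2L * n_wt, 0.5) / (2 * n_wt)
  # n_sims x s matrices of per-site indices; size recycles fastest over sims
  alt_mut <- matrix(stats::rbinom(n_sims * s,
                                  size = rep(depths_mut, each = n_sims),
                                  prob = rep(f_mut, times = s)),
                    nrow = n_sims, ncol = s)
  alt_wt <- matrix(stats::rbinom(n_sims * s,
                                 size = rep(depths_wt, each = n_sims),
                                 prob = rep(f_wt, times = s)),
                   nrow = n_sims, ncol = s)
  idx_mut <- alt_mut / rep(depths_mut, each = n_sims)
  idx_wt <- alt_wt / rep(depths_wt, each = n_sims)
  rowMeans(idx_mut - idx_wt)
}

#' Empirical confidence band from simulated null means
#'
#' Nearest-rank quantiles of the simulated sample: the q-quantile is the
#' `ceiling(q * n)`-th order statistic. Two-sided bands use quantiles at
#' `alpha/2` and `1 - alpha/2`; upper-only bands set `band_lo = -Inf` and
#' `band_hi` to the `1 - alpha` quantile.
#'
#' @param null_means Simulated window means (use at least 100 for stable
#'   tail quantiles; [band_spec()] enforces that on `n_sims`).
#' @param alpha Significance level in (0, 1).
#' @param sidedness `"two_sided_band"` or `"upper_only"`.
#' @return Named numeric vector `c(band_lo, band_hi)`.
#' @export
confidence_band <- function(null_means, alpha = 0.01,
                            sidedness = c("two_sided_band", "upper_only")) {
  sidedness <- match.arg(sidedness)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  stopifnot(length(null_means) >= 1)
  x <- sort(null_means)
  n <- length(x)
  nearest_rank <- function(q) x[max(1L, ceiling(q * n))]
  if (sidedness == "two_sided_band") {
    c(band_lo = nearest_rank(alpha / 2), band_hi = nearest_rank(1 - alpha / 2))
  } else {
    c(band_lo = -Inf, band_hi = nearest_rank(1 - alpha))
  }
}

#' Flag windows against their Monte-Carlo null bands
#'
#' For every non-empty window, simulates the null distribution of the
#' window-mean delta SNP index at the observed per-site depths, computes
#' the band and marks the window significant when its observed mean falls
#' outside. Empty windows get missing bands and are never significant.
#' Deterministic for a fixed `spec$seed`: child seeds are derived per
#' window from it.
#'
#' @param windows Window tibble from [window_means()].
#' @param stats Per-site statistics from [compute_site_stats()] (the same
#'   table the windows were computed from).
#' @param design A [cross_design()] (bulk sizes).
#' @param spec A [band_spec()].
#' @param wspec The [window_spec()] that produced `windows`.
#' @return `windows` with `band_lo`, `band_hi`, `significant` filled.
#' @export
flag_windows <- function(windows, stats, design, spec = band_spec(),
                         wspec = window_spec()) {
  stopifnot(inherits(spec, "band_spec"))
  map <- assign_sites_to_windows(stats, windows, wspec)
  out <- windows
  out$band_lo <- NA_real_
  out$band_hi <- NA_real_
  out$significant <- FALSE
  nonempty <- which(tabulate(map$window, nbins = nrow(windows)) > 0)
  if (length(nonempty) == 0) return(out)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  wseeds <- sample.int(.Machine$integer.max - 1L, length(nonempty))
  site_by_win <- split(map$site, map$window)
  for (j in seq_along(nonempty)) {
    w <- nonempty[j]
    sites <- site_by_win[[as.character(w)]]
    sims <- simulate_null_window(stats$depth_mut[sites], stats$depth_wt[sites],
                                 design, n_sims = spec$n_sims,
                                 seed = wseeds[j])
    band <- confidence_band(sims, spec$alpha, spec$sidedness)
    out$band_lo[w] <- band[["band_lo"]]
    out$band_hi[w] <- band[["band_hi"]]
    m <- out$mean_delta[w]
    out$significant[w] <- if (spec$sidedness == "two_sided_band") {
      m < band[["band_lo"]] || m > band[["band_hi"]]
    } else {
      m > band[["band_hi"]]
    }
  }
  out
}
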