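# Sliding-window smoothing of the per-site delta SNP index.
#
# Windows are anchored at coordinate 0 of each chromosome: window k spans
# [k*step, k*step + size), clipped at the chromosome end. A site at 1-based
# position p belongs to window [a, b) iff a <= p - 1 < b, so an interior
# site contributes to size/step consecutive windows (5 at the defaults).

#' Sliding-window settings
#'
#' @param size Window size in bp (default 25,000).
#' @param step Step between window starts in bp (default 5,000).
#' @return A `window_spec` list.
#' @export
window_spec <- function(size = 25000, step = 5000) {
  stopifnot(step >= 1, size >= step)
  structure(list(size = as.integer(size), step = as.integer(step)),
            class = "window_spec")
}

#' Windows along one chromosome
#'
#' Window k covers `[k*step, k*step + size)` for `k = 0, 1, ...` while
#' `k*step < chrom_length`, with the end clipped to the chromosome length.
#'
#' @param chrom_length Chromosome length in bp.
#' @param spec A [window_spec()].
#' @return A tibble with 0-based half-open `start`, `end`, ordered by start.
#' @export
make_windows <- function(chrom_length, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"), chrom_length >= 1)
  k <- 0:((ceiling(chrom_length / spec$step)) - 1L)
  start <- k * spec$step
  tibble::tibble(start = as.integer(start),
                 end = as.integer(pmin(start + spec$size, chrom_length)))
}

#' Windows for a whole genome
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param spec A [window_spec()].
#' @return A tibble with `chrom`, `start`, `end`, ordered by
#'   (`chrom` in input order, `start`).
#' @export
make_genome_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  dplyr::bind_rows(lapply(names(chrom_lengths), function(cn) {
    w <- make_windows(chrom_lengths[[cn]], spec)
    tibble::tibble(chrom = cn, start = w$start, end = w$end)
  }))
}

# Map each site to the window indices (rows of `windows`) containing it.
# Assumes `windows` is the regular grid produced by make_genome_windows
# with the same spec. Returns a data.frame (site = row in stats,
# window = row in windows).
assign_sites_to_windows <- function(stats, windows, spec) {
  step <- spec$step
  size <- spec$size
  win_key <- paste(windows$chrom, windows$start, sep = "\r")
  p0 <- stats$pos - 1L   # 0-based site coordinate
  k_max <- p0 %/% step
  k_min <- pmax(0L, (p0 - size) %/% step + 1L)
  n_k <- k_max - k_min + 1L
  site_idx <- rep(seq_len(nrow(stats)), n_k)
  k <- unlist(lapply(seq_len(nrow(stats)),
                     function(i) seq(k_min[i], k_max[i])), use.names = FALSE)
  if (length(site_idx) == 0) {
    return(data.frame(site = integer(), window = integer()))
  }
  key <- paste(stats$chrom[site_idx], k * step, sep = "\r")
  win <- match(key, win_key)
  keep <- !is.na(win)
  data.frame(site = site_idx[keep], window = win[keep])
}

#' Window means of the delta SNP index
#'
#' Averages the per-site delta SNP index within each sliding window
#' (unweighted arithmetic mean). Empty windows are reported with
#' `n_sites = 0` and a missing mean.
#'
#' @param stats Per-site statistics from [compute_site_stats()].
#' @param windows Window tibble from [make_genome_windows()].
#' @param spec The [window_spec()] that produced `windows`.
#' @return `windows` with columns `n_sites` and `mean_delta` added.
#' @export
window_means <- function(stats, windows, spec = window_spec()) {
  map <- assign_sites_to_windows(stats, windows, spec)
  n_sites <- tabulate(map$window, nbins = nrow(windows))
  sums <- rep(0, nrow(windows))
  if (nrow(map) > 0) {
    grp <- split(stats$delta[map$site], map$window)
    sums[as.integer(names(grp))] <- vapply(grp, sum, 0, USE.NAMES = FALSE)
  }
  out <- windows
  out$n_sites <- as.integer(n_sites)
  out$mean_delta <- ifelse(n_sites > 0, sums / n_sites, NA_real_)
  out
}
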