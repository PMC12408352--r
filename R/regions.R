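# Candidate-region calling: merge runs of significant windows, report each
# region's peak window, and overlap regions with gene annotation.

#' Merge significant windows into candidate regions
#'
#' Significant windows on the same chromosome whose intervals overlap,
#' touch, or lie within `max_gap` bp of each other are merged; region
#' bounds are the union. The peak is the member window with the largest
#' `mean_delta` (ties broken by smaller start).
#'
#' @param windows Flagged window tibble from [flag_windows()].
#' @param max_gap Maximum gap (bp) bridged when merging (default 0:
#'   adjacent-or-overlapping only).
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `n_windows`, `peak_pos` (start of the peak window), `peak_delta`.
#' @export
merge_significant <- function(windows, max_gap = 0) {
  stopifnot(max_gap >= 0)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_windows = integer(),
                          peak_pos = integer(), peak_delta = numeric())
  sig <- windows[!is.na(windows$significant) & windows$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  sig <- dplyr::arrange(sig, .data$chrom, .data$start)
  new_region <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                    sig$start[-1] > cummax_end(sig)[-nrow(sig)] + max_gap)
  region_id <- cumsum(new_region)
  groups <- split(sig, factor(region_id, levels = unique(region_id)))
  dplyr::bind_rows(lapply(groups, function(g) {
    peak <- which.max(g$mean_delta)   # which.max takes the first on ties
    tibble::tibble(chrom = g$chrom[1],
                   start = as.integer(min(g$start)),
                   end = as.integer(max(g$end)),
                   n_windows = nrow(g),
                   peak_pos = as.integer(g$start[peak]),
                   peak_delta = g$mean_delta[peak])
  }))
}

# running maximum of window ends within each chromosome block, so a window
# nested in an earlier, longer one cannot reopen a region boundary
cummax_end <- function(sig) {
  stats::ave(sig$end, sig$chrom, FUN = cummax)
}

#' Overlap candidate regions with gene annotation
#'
#' A gene with 1-based inclusive coordinates `[start, end]` overlaps a
#' 0-based half-open region `[rs, re)` iff `start - 1 < re` and `end > rs`.
#' Overlapping gene ids are semicolon-joined in gene-start order.
#'
#' @param regions Region tibble from [merge_significant()].
#' @param genes Gene tibble from [read_genes_gff3()].
#' @return `regions` with a `genes` character column added.
#' @export
overlap_genes <- function(regions, genes) {
  out <- regions
  out$genes <- ""
  if (nrow(regions) == 0) return(out)
  if (nrow(genes) > 0) {
    missing_chroms <- setdiff(unique(regions$chrom), unique(genes$chrom))
    if (length(missing_chroms) > 0 &&
        length(intersect(regions$chrom, genes$chrom)) == 0) {
      warning("no shared chromosome names between regions and genes; ",
              "region-only chromosomes: ",
              paste(missing_chroms, collapse = ", "),
              "; gene-only chromosomes: ",
              paste(setdiff(unique(genes$chrom), unique(regions$chrom)),
                    collapse = ", "), call. = FALSE)
    }
  }
  for (i in seq_len(nrow(out))) {
    hit <- genes$chrom == out$chrom[i] &
      (genes$start - 1L) < out$end[i] &
      genes$end > out$start[i]
    g <- genes[hit, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    out$genes[i] <- paste(g$gene_id, collapse = ";")
  }
  out
}
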