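# End-to-end scan: filter -> per-site indices -> sliding windows ->
# Monte-Carlo null bands -> candidate regions.

#' Run the full BSA-seq delta SNP-index scan
#'
#' @param sites Variant tibble from [read_variants_vcf()],
#'   [read_variants_tsv()] or [simulate_bsa_dataset()].
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param design A [cross_design()] (bulk sizes for the null model).
#' @param filter A [filter_spec()].
#' @param window A [window_spec()].
#' @param band A [band_spec()].
#' @param genes Optional gene tibble from [read_genes_gff3()] for
#'   candidate-region overlap.
#' @param max_gap Merge gap for [merge_significant()] (default 0).
#' @return A list with `site_stats`, `windows` (flagged), `regions`, and
#'   `rejected` (per-rule filter rejection counts). Raises a condition of
#'   class `bsascan_empty_filter` when no site survives filtering.
#' @examples
#' cfg <- sim_config(c(chr1 = 2e6), seed = 1)
#' des <- cross_design(causal_chrom = "chr1", causal_pos = 1e6)
#' sim <- simulate_bsa_dataset(des, cfg)
#' scan <- run_bsa_scan(sim$sites, cfg$chrom_lengths, design = des,
#'                      band = band_spec(n_sims = 200, seed = 1))
#' scan$regions
#' @export
run_bsa_scan <- function(sites, chrom_lengths, design = cross_design(),
                         filter = filter_spec(), window = window_spec(),
                         band = band_spec(), genes = NULL, max_gap = 0) {
  kept <- filter_sites(sites, filter)
  if (nrow(kept) == 0) {
    stop(structure(class = c("bsascan_empty_filter", "error", "condition"),
                   list(message = "no sites survive filtering; no windows computable",
                        call = sys.call())))
  }
  stats <- compute_site_stats(kept)
  windows <- make_genome_windows(chrom_lengths, window)
  wm <- window_means(stats, windows, window)
  flagged <- flag_windows(wm, stats, design, band, window)
  regions <- merge_significant(flagged, max_gap = max_gap)
  if (!is.null(genes)) regions <- overlap_genes(regions, genes)
  message("run_bsa_scan: ", nrow(stats), " sites, ",
          sum(flagged$n_sites > 0), "/", nrow(flagged),
          " non-empty windows, ", sum(flagged$significant),
          " significant, ", nrow(regions), " region(s)")
  list(site_stats = stats, windows = flagged, regions = regions,
       rejected = attr(kept, "rejected"))
}
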