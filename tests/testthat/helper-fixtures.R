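# Fixture builders and independent oracles shared across test files.

make_sites <- function(chrom, pos, ref = "G", alt = "A",
                       mut_ref = 0L, mut_alt = 0L, wt_ref = 0L, wt_alt = 0L,
                       qual = NA_real_) {
  n <- max(lengths(list(chrom, pos, mut_ref, mut_alt, wt_ref, wt_alt)))
  bsascan:::new_variant_table(rep_len(chrom, n), rep_len(pos, n),
                              rep_len(ref, n), rep_len(alt, n),
                              rep_len(mut_ref, n), rep_len(mut_alt, n),
                              rep_len(wt_ref, n), rep_len(wt_alt, n),
                              rep_len(qual, n))
}

random_sites <- function(n, chrom_length = 1e6, chroms = "chr1") {
  make_sites(chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(chrom_length, n, replace = TRUE),
             mut_ref = sample.int(40, n, replace = TRUE),
             mut_alt = sample.int(40, n, replace = TRUE),
             wt_ref = sample.int(40, n, replace = TRUE),
             wt_alt = sample.int(40, n, replace = TRUE))
}

# Brute-force window averaging: for each window scan every site. The
# independent oracle for window_means().
brute_window_means <- function(stats, windows) {
  n_sites <- integer(nrow(windows))
  mean_delta <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    member <- stats$chrom == windows$chrom[i] &
      windows$start[i] <= stats$pos - 1 & stats$pos - 1 < windows$end[i]
    n_sites[i] <- sum(member)
    if (n_sites[i] > 0) mean_delta[i] <- sum(stats$delta[member]) / n_sites[i]
  }
  out <- windows
  out$n_sites <- n_sites
  out$mean_delta <- mean_delta
  out
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "mut_pool", "wt_pool", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

vcf_line <- function(chrom = "chr1", pos = 1000, ref = "G", alt = "A",
                     qual = "50", mut_ad = "0,12", wt_ad = "6,6",
                     format = "AD") {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", format,
        mut_ad, wt_ad, sep = "\t")
}

write_test_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(chrom = "chr3", type = "gene", start = 1620001,
                     end = 1640000, strand = "+", attrs = "ID=OsCNL1") {
  paste(chrom, ".", type, start, end, ".", strand, ".", attrs, sep = "\t")
}
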