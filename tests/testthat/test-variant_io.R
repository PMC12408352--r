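test_that("VCF records transcribe AD counts verbatim", {
  path <- write_test_vcf(vcf_line(pos = 1000, ref = "G", alt = "A",
                                  mut_ad = "0,12", wt_ad = "6,6"))
  v <- read_variants_vcf(path, "mut_pool", "wt_pool")
  expect_equal(nrow(v), 1)
  expect_equal(v$pos, 1000L)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "A")
  expect_equal(c(v$mut_ref, v$mut_alt), c(0L, 12L))
  expect_equal(c(v$wt_ref, v$wt_alt), c(6L, 6L))
  expect_equal(sum(attr(v, "skipped")), 0L)
})

test_that("multi-allelic, indel and AD-less VCF records are skipped and counted", {
  path <- write_test_vcf(c(
    vcf_line(pos = 100),
    vcf_line(pos = 200, alt = "A,T", mut_ad = "1,2,3", wt_ad = "4,5,6"),
    vcf_line(pos = 300, ref = "GA", alt = "G", mut_ad = "3,4", wt_ad = "5,6"),
    vcf_line(pos = 400, format = "GT", mut_ad = "0/1", wt_ad = "0/1")))
  v <- suppressMessages(read_variants_vcf(path, "mut_pool", "wt_pool"))
  expect_equal(v$pos, 100L)
  skipped <- attr(v, "skipped")
  expect_equal(skipped[["multiallelic"]], 1L)
  expect_equal(skipped[["non_snp"]], 1L)
  expect_equal(skipped[["missing_ad"]], 1L)
})

test_that("a site lacking AD in one pool is excluded from both", {
  path <- write_test_vcf(c(
    vcf_line(pos = 100, format = "GT:AD", mut_ad = "1/1:0,12", wt_ad = "0/1:."),
    vcf_line(pos = 200)))
  v <- suppressMessages(read_variants_vcf(path, "mut_pool", "wt_pool"))
  expect_equal(v$pos, 200L)
  expect_equal(attr(v, "skipped")[["missing_ad"]], 1L)
})

test_that("header-only VCF yields an empty table with zero skips", {
  path <- write_test_vcf(character(0))
  v <- read_variants_vcf(path, "mut_pool", "wt_pool")
  expect_equal(nrow(v), 0)
  expect_equal(sum(attr(v, "skipped")), 0L)
})

test_that("a missing VCF sample is fatal and names the available samples", {
  path <- write_test_vcf(vcf_line())
  expect_error(read_variants_vcf(path, "nope", "wt_pool"),
               "available samples.*mut_pool.*wt_pool")
})

test_that("TSV rows transcribe directly and bad counts are fatal with line numbers", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tmut_ref\tmut_alt\twt_ref\twt_alt",
               "chr3\t1620000\tG\tA\t0\t30\t20\t10"), path)
  v <- read_variants_tsv(path)
  expect_equal(v$chrom, "chr3")
  expect_equal(v$pos, 1620000L)
  expect_equal(c(v$mut_ref, v$mut_alt, v$wt_ref, v$wt_alt),
               c(0L, 30L, 20L, 10L))

  writeLines(c("chrom\tpos\tref\talt\tmut_ref\tmut_alt\twt_ref\twt_alt",
               "chr3\t100\tG\tA\t0\t30\t20\t10",
               "chr3\t200\tG\tA\t0\tNA\t20\t10"), path)
  expect_error(read_variants_tsv(path), "line 3")

  writeLines("chrom\tpos\tref\talt\tmut_ref\tmut_alt\twt_ref\twt_alt", path)
  expect_equal(nrow(read_variants_tsv(path)), 0)
})

test_that("a malformed TSV header is fatal and lists the expected columns", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tmutant_ref",
               "chr1\t1\tG\tA\t3"), path)
  expect_error(read_variants_tsv(path), "mut_ref.*expected columns")
})

test_that("TSV write/read round trip is the identity on random site tables", {
  set.seed(1)
  for (i in 1:20) {
    x <- random_sites(sample(0:50, 1), chroms = c("chr1", "chr2"))
    path <- tempfile(fileext = ".tsv")
    write_variants_tsv(x, path)
    y <- read_variants_tsv(path)
    expect_equal(as.data.frame(y), as.data.frame(x))
  }
})

test_that("VCF write/read round trip preserves counts and order", {
  set.seed(2)
  x <- random_sites(30, chroms = c("chr1", "chr2"))
  x <- x[order(match(x$chrom, c("chr1", "chr2")), x$pos), ]
  x <- x[!duplicated(paste(x$chrom, x$pos)), ]
  x$qual <- 99
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(x, path, chrom_lengths = c(chr1 = 1e6, chr2 = 1e6))
  y <- read_variants_vcf(path, "mut_pool", "wt_pool")
  attr(y, "skipped") <- NULL
  expect_equal(as.data.frame(y), as.data.frame(x))
})

test_that("GFF3 reader keeps only gene features with preserved 1-based coordinates", {
  path <- write_test_gff3(c(
    gff_line(start = 1620001, end = 1640000, attrs = "ID=OsCNL1"),
    gff_line(type = "mRNA", start = 1620001, end = 1640000,
             attrs = "ID=OsCNL1.1;Parent=OsCNL1")))
  g <- read_genes_gff3(path)
  expect_equal(nrow(g), 1)
  expect_equal(g$start, 1620001L)
  expect_equal(g$end, 1640000L)
  expect_equal(g$gene_id, "OsCNL1")
  expect_equal(g$strand, "+")
})

test_that("GFF3 reader skips unparseable lines with a count and handles empty files", {
  path <- write_test_gff3(c(gff_line(), "not a gff line"))
  g <- suppressMessages(read_genes_gff3(path))
  expect_equal(nrow(g), 1)
  expect_equal(attr(g, "skipped"), 1L)

  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_genes_gff3(empty)), 0)
})

test_that("window table is sorted by (chrom, start) with 0-based half-open intervals", {
  w <- tibble::tibble(chrom = c("chr2", "chr1", "chr1"),
                      start = c(0L, 5000L, 0L), end = c(25000L, 30000L, 25000L),
                      n_sites = c(1L, 2L, 3L), mean_delta = c(0.1, 0.2, 0.3),
                      band_lo = NA_real_, band_hi = NA_real_,
                      significant = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_window_table(w, path)
  out <- utils::read.delim(path)
  expect_equal(out$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(out$start, c(0L, 5000L, 0L))
  expect_true(all(out$end - out$start > 0))
  expect_true(all(out$start >= 0))

  empty <- tempfile(fileext = ".tsv")
  write_window_table(w[0, ], empty)
  expect_equal(length(readLines(empty)), 1)  # header only
})
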