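# I/O for the formats the scan touches: two-sample VCF with AD, the
# allele-count TSV, GFF3 gene annotation, and the window/region tables.
#
# Coordinate conventions: VCF/GFF3 and all in-memory positions are 1-based;
# every exported interval file (window table, region table, BED) is 0-based
# half-open, as BED requires.

VARIANT_TSV_COLS <- c("chrom", "pos", "ref", "alt",
                      "mut_ref", "mut_alt", "wt_ref", "wt_alt")

new_variant_table <- function(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              mut_ref = integer(), mut_alt = integer(),
                              wt_ref = integer(), wt_alt = integer(),
                              qual = rep(NA_real_, length(chrom))) {
  tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 mut_ref = as.integer(mut_ref), mut_alt = as.integer(mut_alt),
                 wt_ref = as.integer(wt_ref), wt_alt = as.integer(wt_alt),
                 qual = as.numeric(qual))
}

validate_variants <- function(x) {
  stopifnot(all(VARIANT_TSV_COLS %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  counts <- c(x$mut_ref, x$mut_alt, x$wt_ref, x$wt_alt)
  if (anyNA(counts) || any(counts < 0)) {
    stop("allele counts must be non-negative integers", call. = FALSE)
  }
  if (any(x$pos < 1)) stop("positions must be >= 1 (1-based)", call. = FALSE)
  if (any(x$ref == x$alt)) stop("ref and alt alleles must differ", call. = FALSE)
  invisible(x)
}

#' Read two-pool variant sites from a VCF
#'
#' Parses a VCF with at least two samples carrying the standard per-sample
#' allelic-depth (`AD`) field and returns one row per biallelic SNP, with
#' ref/alt read counts for the mutant-phenotype and wild-type-phenotype pools
#' taken verbatim from `AD`. Multi-allelic records, non-SNP records (indels,
#' symbolic alleles) and records lacking `AD` in either pool are skipped and
#' counted; the counts are attached as the `"skipped"` attribute.
#'
#' @param path Path to a VCF (plain text or bgzip).
#' @param mut_sample,wt_sample Sample names of the mutant-phenotype and
#'   wild-type-phenotype pools as they appear in the VCF header.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`, `qual` (NA when the QUAL
#'   column is "."), ordered as in the file, with attribute `skipped`
#'   (named integer: `multiallelic`, `non_snp`, `missing_ad`).
#' @export
read_variants_vcf <- function(path, mut_sample, wt_sample) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  skipped <- c(multiallelic = 0L, non_snp = 0L, missing_ad = 0L)
  empty <- new_variant_table()
  if (nrow(vcf@fix) == 0) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  samples <- colnames(vcf@gt)[-1]
  for (s in c(mut_sample, wt_sample)) {
    if (!s %in% samples) {
      stop("sample '", s, "' not found in VCF; available samples: ",
           paste(samples, collapse = ", "), call. = FALSE)
    }
  }
  fix <- vcf@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  bases <- c("A", "C", "G", "T")
  snp <- !multi & ref %in% bases & alt %in% bases

  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad_mut <- ad[, mut_sample]
  ad_wt <- ad[, wt_sample]
  # missing AD in either pool excludes the site from both (delta needs both)
  has_ad <- !is.na(ad_mut) & !is.na(ad_wt) & ad_mut != "." & ad_wt != "."

  skipped["multiallelic"] <- sum(multi)
  skipped["non_snp"] <- sum(!snp & !multi)
  skipped["missing_ad"] <- sum(snp & !has_ad)

  keep <- snp & has_ad
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, "", 1L)),
         alt = as.integer(vapply(parts, `[`, "", 2L)))
  }
  if (!any(keep)) {
    out <- empty
  } else {
    m <- split_ad(ad_mut[keep])
    w <- split_ad(ad_wt[keep])
    out <- new_variant_table(chrom[keep], pos[keep], ref[keep], alt[keep],
                             m$ref, m$alt, w$ref, w$alt, qual[keep])
  }
  if (sum(skipped) > 0) {
    message("read_variants_vcf: skipped ", sum(skipped), " record(s) (",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  }
  validate_variants(out)
  attr(out, "skipped") <- skipped
  out
}

#' Read two-pool variant sites from an allele-count TSV
#'
#' The table must be tab-separated with a header row naming (at least) the
#' columns `chrom`, `pos`, `ref`, `alt`, `mut_ref`, `mut_alt`, `wt_ref`,
#' `wt_alt`; an optional `qual` column is carried through. Any row whose
#' count or position fields are not integers is a fatal parse error naming
#' the offending line.
#'
#' @param path Path to the TSV file.
#' @return A tibble as in [read_variants_vcf()].
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(VARIANT_TSV_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), "; expected columns: ",
         paste(VARIANT_TSV_COLS, collapse = ", "), call. = FALSE)
  }
  int_cols <- c("pos", "mut_ref", "mut_alt", "wt_ref", "wt_alt")
  parsed <- lapply(df[int_cols], function(x) suppressWarnings(as.integer(x)))
  for (col in int_cols) {
    bad <- which(is.na(parsed[[col]]))
    if (length(bad) > 0) {
      stop("non-integer value '", df[[col]][bad[1]], "' in column '", col,
           "' at line ", bad[1] + 1L, " of ", path, call. = FALSE)
    }
  }
  qual <- if ("qual" %in% names(df)) {
    suppressWarnings(as.numeric(df$qual))
  } else {
    rep(NA_real_, nrow(df))
  }
  out <- new_variant_table(df$chrom, parsed$pos, df$ref, df$alt,
                           parsed$mut_ref, parsed$mut_alt,
                           parsed$wt_ref, parsed$wt_alt, qual)
  validate_variants(out)
  out
}

#' Write variant sites to the allele-count TSV
#'
#' Inverse of [read_variants_tsv()]: writing then reading reproduces the
#' input table (the optional `qual` column is written only when any value
#' is present).
#'
#' @param x Variant tibble (see [read_variants_tsv()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(x, path) {
  validate_variants(x)
  cols <- VARIANT_TSV_COLS
  if ("qual" %in% names(x) && any(!is.na(x$qual))) cols <- c(cols, "qual")
  utils::write.table(as.data.frame(x)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Keeps only features of type `gene`; 1-based inclusive coordinates are
#' preserved. Lines that are not valid 9-column GFF records are skipped and
#' counted (attribute `skipped`). The gene identifier is taken from the
#' `ID=` attribute (falling back to `Name=`).
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `gene_id`.
#' @export
read_genes_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  nfields <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- nfields != 9L
  if (any(bad)) {
    message("read_genes_gff3: skipped ", sum(bad), " unparseable line(s)")
  }
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          gene_id = character())
  body <- body[!bad]
  if (length(body) == 0) {
    attr(empty, "skipped") <- sum(bad)
    return(empty)
  }
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  writeLines(c("##gff-version 3", body), tmp)
  gff <- ape::read.gff(tmp, GFF3 = TRUE)
  gff <- gff[gff$type == "gene", , drop = FALSE]
  ids <- vapply(as.character(gff$attributes), function(a) {
    for (key in c("ID", "Name")) {
      hit <- regmatches(a, regexpr(paste0("(?:^|;)\\s*", key, "=([^;]+)"), a, perl = TRUE))
      if (length(hit) > 0) return(sub(paste0("^.*", key, "="), "", hit))
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  out <- tibble::tibble(chrom = as.character(gff$seqid),
                        start = as.integer(gff$start),
                        end = as.integer(gff$end),
                        strand = as.character(gff$strand),
                        gene_id = ids)
  stopifnot(all(out$start <= out$end))
  attr(out, "skipped") <- sum(bad)
  out
}

#' Write the window-statistic table
#'
#' TSV with columns `chrom`, `start` (0-based), `end` (exclusive), `n_sites`,
#' `mean_delta`, `band_lo`, `band_hi`, `significant`, sorted by
#' (`chrom`, `start`). Intervals are 0-based half-open.
#'
#' @param windows Window tibble from [window_means()] / [flag_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  cols <- c("chrom", "start", "end", "n_sites", "mean_delta",
            "band_lo", "band_hi", "significant")
  w <- windows
  for (col in setdiff(cols, names(w))) {
    w[[col]] <- if (col == "significant") NA else NA_real_
  }
  w <- dplyr::arrange(w[, cols], .data$chrom, .data$start)
  stopifnot(all(w$start >= 0), all(w$end > w$start))
  utils::write.table(as.data.frame(w), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write per-site SNP-index statistics to TSV
#'
#' @param stats Site-statistic tibble from [compute_site_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(stats, path) {
  cols <- c("chrom", "pos", "depth_mut", "depth_wt",
            "index_mut", "index_wt", "delta")
  utils::write.table(as.data.frame(stats)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write candidate regions as TSV and/or BED
#'
#' The TSV carries the merged-region bookkeeping (window count, peak position
#' and peak delta, semicolon-joined overlapping genes); the BED is the plain
#' 0-based half-open interval track with the peak delta as score.
#'
#' @param regions Region tibble from [merge_significant()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  r <- regions
  if (!"genes" %in% names(r)) r$genes <- ""
  cols <- c("chrom", "start", "end", "n_windows", "peak_pos", "peak_delta", "genes")
  r <- dplyr::arrange(r[, cols], .data$chrom, .data$start)
  utils::write.table(as.data.frame(r), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_region_table
#' @export
write_region_bed <- function(regions, path) {
  stopifnot(all(regions$start >= 0), all(regions$end > regions$start))
  r <- dplyr::arrange(regions, .data$chrom, .data$start)
  bed <- data.frame(chrom = r$chrom, start = r$start, end = r$end,
                    name = sprintf("region_%d", seq_len(nrow(r))),
                    score = r$peak_delta)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write variant sites as a minimal two-sample VCF
#'
#' Emits a VCFv4.2 text with per-sample `AD` fields for the two pools, the
#' dialect [read_variants_vcf()] consumes.
#'
#' @param x Variant tibble.
#' @param path Output path.
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @param mut_sample,wt_sample Sample names to write.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(x, path, chrom_lengths = NULL,
                               mut_sample = "mut_pool", wt_sample = "wt_pool") {
  validate_variants(x)
  header <- c("##fileformat=VCFv4.2",
              "##source=bsascan",
              '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">')
  if (!is.null(chrom_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(chrom_lengths), as.integer(chrom_lengths)))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT",
                              mut_sample, wt_sample), collapse = "\t"))
  qual <- ifelse(is.na(x$qual), ".", format(x$qual, trim = TRUE))
  body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, qual, "PASS", ".", "AD",
                paste0(x$mut_ref, ",", x$mut_alt),
                paste0(x$wt_ref, ",", x$wt_alt), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
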