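# Per-site SNP index and delta SNP index.
#
# The SNP index of a pool at a site is the fraction of reads carrying the
# mutant (ALT) allele: alt / (ref + alt). The delta SNP index is the
# mutant-pool index minus the wild-type-pool index; it sits near 0 at
# unlinked loci and rises toward its linkage maximum at the causal locus
# (2/3 in expectation for recessive bulks from a 1:2:1 F2).

#' Depth/quality filter settings
#'
#' @param min_depth_per_pool Minimum read depth required in *both* pools
#'   (default 8).
#' @param min_site_quality Minimum variant quality score, applied only to
#'   sites that carry a quality value (default 20).
#' @param restrict_to_ems_spectrum If `TRUE`, keep only G>A / C>T
#'   substitutions, the EMS point-mutation spectrum (default `FALSE`).
#' @param min_index_floor Optional floor on the larger of the two pool
#'   indices; `NULL` (default) disables it. Some BSA-seq protocols drop
#'   sites where both pools are near-reference; off by default.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_depth_per_pool = 8, min_site_quality = 20,
                        restrict_to_ems_spectrum = FALSE,
                        min_index_floor = NULL) {
  stopifnot(min_depth_per_pool >= 0, min_site_quality >= 0)
  if (!is.null(min_index_floor)) {
    stopifnot(min_index_floor >= 0, min_index_floor <= 1)
  }
  structure(list(min_depth_per_pool = min_depth_per_pool,
                 min_site_quality = min_site_quality,
                 restrict_to_ems_spectrum = restrict_to_ems_spectrum,
                 min_index_floor = min_index_floor),
            class = "filter_spec")
}

#' SNP index of one pool at one site
#'
#' @param ref_count,alt_count Reference- and alternate-allele read counts
#'   (vectors recycle as usual).
#' @return `alt_count / (ref_count + alt_count)`, in `[0, 1]`.
#' @export
snp_index <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  if (any(total <= 0)) {
    stop("SNP index undefined at zero total depth; filter such sites first",
         call. = FALSE)
  }
  alt_count / total
}

#' Delta SNP index
#'
#' Mutant-pool SNP index minus wild-type-pool SNP index.
#'
#' @param index_mut,index_wt Per-site SNP indices, each in `[0, 1]`.
#' @return `index_mut - index_wt`, in `[-1, 1]`.
#' @export
delta_snp_index <- function(index_mut, index_wt) {
  stopifnot(all(index_mut >= 0 & index_mut <= 1),
            all(index_wt >= 0 & index_wt <= 1))
  index_mut - index_wt
}

#' Filter variant sites before index computation
#'
#' Applies, in order: the per-pool depth rule, the site-quality rule (only
#' where a quality value is present), the EMS-spectrum rule, and the optional
#' index floor. A rejected site is attributed to the first rule it fails;
#' per-rule counts are attached as the `"rejected"` attribute.
#'
#' @param sites Variant tibble (see [read_variants_tsv()]).
#' @param spec A [filter_spec()].
#' @return The kept sites, with attribute `rejected` (named integer vector
#'   with elements `depth`, `quality`, `spectrum`, `index_floor`).
#' @export
filter_sites <- function(sites, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  depth_mut <- sites$mut_ref + sites$mut_alt
  depth_wt <- sites$wt_ref + sites$wt_alt
  fail_depth <- depth_mut < spec$min_depth_per_pool |
    depth_wt < spec$min_depth_per_pool
  qual <- if ("qual" %in% names(sites)) sites$qual else rep(NA_real_, nrow(sites))
  fail_qual <- !is.na(qual) & qual < spec$min_site_quality
  ems <- (sites$ref == "G" & sites$alt == "A") |
    (sites$ref == "C" & sites$alt == "T")
  fail_spectrum <- if (spec$restrict_to_ems_spectrum) !ems else rep(FALSE, nrow(sites))
  fail_floor <- if (!is.null(spec$min_index_floor)) {
    ok <- depth_mut > 0 & depth_wt > 0
    f <- rep(TRUE, nrow(sites))
    f[ok] <- pmax(sites$mut_alt[ok] / depth_mut[ok],
                  sites$wt_alt[ok] / depth_wt[ok]) < spec$min_index_floor
    f
  } else {
    rep(FALSE, nrow(sites))
  }

  first_fail <- rep(NA_character_, nrow(sites))
  first_fail[fail_floor] <- "index_floor"
  first_fail[fail_spectrum] <- "spectrum"
  first_fail[fail_qual] <- "quality"
  first_fail[fail_depth] <- "depth"

  rejected <- c(depth = sum(first_fail == "depth", na.rm = TRUE),
                quality = sum(first_fail == "quality", na.rm = TRUE),
                spectrum = sum(first_fail == "spectrum", na.rm = TRUE),
                index_floor = sum(first_fail == "index_floor", na.rm = TRUE))
  kept <- sites[is.na(first_fail), , drop = FALSE]
  if (sum(rejected) > 0) {
    message("filter_sites: rejected ", sum(rejected), " of ", nrow(sites),
            " site(s) (", paste(names(rejected), rejected, sep = "=",
                                collapse = ", "), ")")
  }
  attr(kept, "rejected") <- rejected
  kept
}

#' Per-site SNP-index statistics
#'
#' Computes both pool indices and the delta SNP index for every site; all
#' sites must be covered in both pools (run [filter_sites()] first).
#'
#' @param sites Filtered variant tibble.
#' @return A tibble with columns `chrom`, `pos`, `depth_mut`, `depth_wt`,
#'   `index_mut`, `index_wt`, `delta`, in input order.
#' @export
compute_site_stats <- function(sites) {
  depth_mut <- sites$mut_ref + sites$mut_alt
  depth_wt <- sites$wt_ref + sites$wt_alt
  if (any(depth_mut == 0 | depth_wt == 0)) {
    stop("zero-depth site reached compute_site_stats(); ",
         "filter_sites() must be applied first", call. = FALSE)
  }
  if (nrow(sites) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          depth_mut = integer(), depth_wt = integer(),
                          index_mut = numeric(), index_wt = numeric(),
                          delta = numeric()))
  }
  index_mut <- snp_index(sites$mut_ref, sites$mut_alt)
  index_wt <- snp_index(sites$wt_ref, sites$wt_alt)
  tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                 depth_mut = as.integer(depth_mut),
                 depth_wt = as.integer(depth_wt),
                 index_mut = index_mut, index_wt = index_wt,
                 delta = delta_snp_index(index_mut, index_wt))
}
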