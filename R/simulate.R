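# Forward simulator of the BSA-seq experiment: EMS point variants on a
# genome, a selfed-heterozygote (BC1F1 selfed) population segregating
# 1:2:1 in genotype and 3:1 in phenotype for a fully penetrant recessive,
# phenotype-selected bulks, and short-read allele sampling per site.
#
# Recombination is simulated marker-by-marker relative to the causal locus
# only (a star topology), with the Haldane map function converting physical
# distance to recombination fraction. That reproduces the sampling
# distribution of per-site bulk frequencies without modelling interference
# or full meioses.

#' Experimental cross design
#'
#' The selfed-heterozygote model: a backcross F1 heterozygous at the causal
#' locus is selfed, giving 1 AA : 2 Aa : 1 aa genotypes and a 3:1
#' wild-type : mutant phenotype ratio for a fully penetrant recessive.
#' Bulk sizes default to the 44 mutant-phenotype / 50 wild-type-phenotype
#' lines of the mapping experiment the package models.
#'
#' @param mut_bulk_size Lines in the mutant-phenotype bulk (default 44).
#' @param wt_bulk_size Lines in the wild-type-phenotype bulk (default 50).
#' @param causal_chrom Chromosome of the causal locus; `NA` simulates a
#'   null experiment with no causal locus (all sites unlinked, phenotype
#'   independent of genotype).
#' @param causal_pos 1-based position of the causal locus.
#' @param segregation_model Only `"F2_SELFED"` is implemented.
#' @return A `cross_design` list.
#' @export
cross_design <- function(mut_bulk_size = 44, wt_bulk_size = 50,
                         causal_chrom = "chr3", causal_pos = 1630000,
                         segregation_model = "F2_SELFED") {
  segregation_model <- match.arg(segregation_model, "F2_SELFED")
  stopifnot(mut_bulk_size >= 1, wt_bulk_size >= 1)
  if (!is.na(causal_chrom)) stopifnot(causal_pos >= 1)
  structure(list(mut_bulk_size = as.integer(mut_bulk_size),
                 wt_bulk_size = as.integer(wt_bulk_size),
                 causal_chrom = causal_chrom,
                 causal_pos = as.integer(causal_pos),
                 segregation_model = segregation_model),
            class = "cross_design")
}

#' Simulation settings
#'
#' Defaults describe a rice-scale EMS experiment: about one induced variant
#' per 50 kb, 95% of them G:C->A:T transitions, a 4 cM/Mb genetic map,
#' mean per-site per-pool depth 30 and a 0.2% per-read miscall rate.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param variant_density Expected variants per bp (default 1/50,000).
#' @param ems_gc_to_at_fraction Probability a variant is G>A or C>T
#'   (default 0.95).
#' @param cm_per_mb Genetic-map rate in centimorgan per megabase (default 4).
#' @param depth_mean Poisson mean of per-site per-pool read depth (default 30).
#' @param error_rate Per-read miscall probability (default 0.002).
#' @param seed Root seed; every stochastic stage of the simulator draws
#'   from the stream it initialises (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths, variant_density = 1 / 50000,
                       ems_gc_to_at_fraction = 0.95, cm_per_mb = 4,
                       depth_mean = 30, error_rate = 0.002, seed = 1L) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)),
            all(chrom_lengths >= 1),
            variant_density >= 0,
            ems_gc_to_at_fraction >= 0, ems_gc_to_at_fraction <= 1,
            cm_per_mb >= 0, depth_mean >= 0,
            error_rate >= 0, error_rate <= 1)
  structure(list(chrom_lengths = chrom_lengths,
                 variant_density = variant_density,
                 ems_gc_to_at_fraction = ems_gc_to_at_fraction,
                 cm_per_mb = cm_per_mb, depth_mean = depth_mean,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Recombination fraction from physical distance (Haldane)
#'
#' `r = (1 - exp(-2d)) / 2` with `d` in Morgans:
#' `d = distance_bp / 1e6 * cm_per_mb / 100`.
#'
#' @param distance_bp Physical distance in bp (non-negative; `Inf` gives 0.5).
#' @param cm_per_mb Map rate in cM/Mb.
#' @return Recombination fraction in `[0, 0.5]`.
#' @export
recomb_fraction <- function(distance_bp, cm_per_mb) {
  if (any(distance_bp < 0, na.rm = TRUE)) {
    stop("distance_bp must be non-negative", call. = FALSE)
  }
  d <- distance_bp * cm_per_mb * 1e-8
  0.5 * (1 - exp(-2 * d))
}

ems_pairs <- matrix(c("G", "A", "C", "T"), nrow = 2, byrow = TRUE)

other_pairs <- local({
  bases <- c("A", "C", "G", "T")
  all <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  all <- all[all$ref != all$alt, ]
  all[!(all$ref == "G" & all$alt == "A") & !(all$ref == "C" & all$alt == "T"), ]
})

#' Place EMS variants on the genome
#'
#' Per chromosome the variant count is Poisson(density x length) and
#' positions are uniform without duplicates. With probability
#' `ems_gc_to_at_fraction` a variant is a G>A or C>T transition (equally
#' likely), otherwise one of the ten other substitutions uniformly. If the
#' design names a causal locus, a G>A variant is always placed there,
#' replacing any background variant at the same position.
#'
#' @param config A [sim_config()].
#' @param design A [cross_design()]; `NULL` or a design with
#'   `causal_chrom = NA` places no causal variant.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt`, `is_causal`, sorted
#'   by (`chrom` in `chrom_lengths` order, `pos`).
#' @export
place_variants <- function(config, design = NULL) {
  stopifnot(inherits(config, "sim_config"))
  has_causal <- !is.null(design) && !is.na(design$causal_chrom)
  if (has_causal) {
    if (!design$causal_chrom %in% names(config$chrom_lengths)) {
      stop("causal_chrom '", design$causal_chrom,
           "' is not in chrom_lengths", call. = FALSE)
    }
    if (design$causal_pos > config$chrom_lengths[[design$causal_chrom]]) {
      stop("causal_pos exceeds its chromosome length", call. = FALSE)
    }
  }
  per_chrom <- lapply(names(config$chrom_lengths), function(cn) {
    len <- config$chrom_lengths[[cn]]
    n <- stats::rpois(1, config$variant_density * len)
    if (n > len) {
      stop("variant density too high: cannot place ", n,
           " unique positions on ", len, " bp", call. = FALSE)
    }
    if (n == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character()))
    }
    pos <- sort(sample.int(len, n))
    is_ems <- stats::runif(n) < config$ems_gc_to_at_fraction
    ref <- alt <- character(n)
    if (any(is_ems)) {
      which_pair <- sample(1:2, sum(is_ems), replace = TRUE)
      ref[is_ems] <- ems_pairs[which_pair, 1]
      alt[is_ems] <- ems_pairs[which_pair, 2]
    }
    if (any(!is_ems)) {
      which_other <- sample(nrow(other_pairs), sum(!is_ems), replace = TRUE)
      ref[!is_ems] <- other_pairs$ref[which_other]
      alt[!is_ems] <- other_pairs$alt[which_other]
    }
    tibble::tibble(chrom = cn, pos = as.integer(pos), ref = ref, alt = alt)
  })
  out <- dplyr::bind_rows(per_chrom)
  out$is_causal <- FALSE
  if (has_causal) {
    clash <- out$chrom == design$causal_chrom & out$pos == design$causal_pos
    out <- out[!clash, , drop = FALSE]
    out <- dplyr::bind_rows(out, tibble::tibble(
      chrom = design$causal_chrom, pos = design$causal_pos,
      ref = "G", alt = "A", is_causal = TRUE))
    out <- out[order(match(out$chrom, names(config$chrom_lengths)), out$pos), ]
  }
  out
}

# Draw BC1F2 individuals (causal-genotype classes) until both
# phenotype-selected bulks are filled. Genotype coded as the count of
# mutant alleles: 0 = AA, 1 = Aa, 2 = aa; phenotype mutant iff 2.
draw_bulk_genotypes <- function(design, max_attempts = 1e6) {
  need_mut <- design$mut_bulk_size
  need_wt <- design$wt_bulk_size
  mut_g <- integer(0)
  wt_g <- integer(0)
  attempts <- 0L
  batch <- 512L
  while (length(mut_g) < need_mut || length(wt_g) < need_wt) {
    if (attempts >= max_attempts) {
      stop("could not fill bulks within ", max_attempts, " individuals",
           call. = FALSE)
    }
    g <- sample(0:2, batch, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    attempts <- attempts + batch
    mut_g <- c(mut_g, g[g == 2L])[seq_len(min(need_mut, length(mut_g) + sum(g == 2L)))]
    wt_g <- c(wt_g, g[g < 2L])[seq_len(min(need_wt, length(wt_g) + sum(g < 2L)))]
  }
  list(mut = mut_g, wt = wt_g)
}

#' Simulate the segregating population and true bulk allele frequencies
#'
#' Each individual draws a causal genotype (1/4 AA : 1/2 Aa : 1/4 aa);
#' the phenotype is mutant iff homozygous mutant. Individuals are drawn
#' until both phenotype-selected bulks are filled. At every other variant
#' each gamete carries the allele in phase with its causal allele with
#' probability `1 - r` (Haldane `r` from physical distance on the causal
#' chromosome, `r = 0.5` elsewhere), and the true bulk frequency is the
#' mutant-allele count over `2 x bulk size`. With `causal_chrom = NA` all
#' sites are unlinked and bulks are random draws from the population.
#'
#' @param design A [cross_design()].
#' @param variants Variant table from [place_variants()].
#' @param config A [sim_config()].
#' @return The truth table: `variants` plus `dist_bp` (NA off the causal
#'   chromosome), `r`, `f_mut`, `f_wt`.
#' @export
simulate_population <- function(design, variants, config) {
  stopifnot(inherits(design, "cross_design"), inherits(config, "sim_config"))
  m <- nrow(variants)
  n_mut2 <- 2L * design$mut_bulk_size
  n_wt2 <- 2L * design$wt_bulk_size
  out <- variants
  if (is.na(design$causal_chrom)) {
    out$dist_bp <- NA_real_
    out$r <- rep(0.5, m)
    out$f_mut <- stats::rbinom(m, n_mut2, 0.5) / n_mut2
    out$f_wt <- stats::rbinom(m, n_wt2, 0.5) / n_wt2
    return(out)
  }
  if (!any(variants$is_causal)) {
    stop("variants contain no causal site; run place_variants() with the design",
         call. = FALSE)
  }
  bulks <- draw_bulk_genotypes(design)
  # gametes carrying the mutant allele at the causal locus, per bulk
  a_mut <- sum(bulks$mut)          # = 2 * mut_bulk_size (all aa)
  a_wt <- sum(bulks$wt)
  dist <- ifelse(variants$chrom == design$causal_chrom,
                 abs(variants$pos - design$causal_pos), NA_real_)
  r <- ifelse(is.na(dist), 0.5, recomb_fraction(dist, config$cm_per_mb))
  # marker mutant-allele count: in-phase gametes keep the mutant allele with
  # prob 1-r, out-of-phase gametes pick it up with prob r
  x_mut <- stats::rbinom(m, a_mut, 1 - r) + stats::rbinom(m, n_mut2 - a_mut, r)
  x_wt <- stats::rbinom(m, a_wt, 1 - r) + stats::rbinom(m, n_wt2 - a_wt, r)
  out$dist_bp <- dist
  out$r <- r
  out$f_mut <- x_mut / n_mut2
  out$f_wt <- x_wt / n_wt2
  out
}

#' Simulate read counts over the true bulk frequencies
#'
#' Per site and pool, depth is Poisson(`depth_mean`) and the alt-read count
#' is binomial at `f(1 - e) + (1 - f)e` with miscall rate `e`. Zero-depth
#' sites are emitted (downstream filters decide their fate).
#'
#' @param truth Truth table from [simulate_population()].
#' @param config A [sim_config()].
#' @return A variant tibble (schema of [read_variants_tsv()], `qual = NA`).
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- nrow(truth)
  e <- config$error_rate
  depth_mut <- stats::rpois(m, config$depth_mean)
  depth_wt <- stats::rpois(m, config$depth_mean)
  p_mut <- truth$f_mut * (1 - e) + (1 - truth$f_mut) * e
  p_wt <- truth$f_wt * (1 - e) + (1 - truth$f_wt) * e
  alt_mut <- stats::rbinom(m, depth_mut, p_mut)
  alt_wt <- stats::rbinom(m, depth_wt, p_wt)
  new_variant_table(truth$chrom, truth$pos, truth$ref, truth$alt,
                    depth_mut - alt_mut, alt_mut,
                    depth_wt - alt_wt, alt_wt)
}

#' Simulate a complete BSA-seq dataset
#'
#' Runs [place_variants()], [simulate_population()] and [simulate_reads()]
#' under the root seed in `config`; the result is deterministic for a fixed
#' seed.
#'
#' @param design A [cross_design()].
#' @param config A [sim_config()].
#' @return A list with `sites` (observable variant table) and `truth`
#'   (hidden truth table).
#' @export
simulate_bsa_dataset <- function(design, config) {
  set.seed(config$seed)
  variants <- place_variants(config, design)
  truth <- simulate_population(design, variants, config)
  sites <- simulate_reads(truth, config)
  list(sites = sites, truth = truth)
}

#' Generate a dataset on disk
#'
#' Writes the observable data (`<prefix>_variants.tsv` and optionally
#' `<prefix>.vcf`) and the hidden truth (`<prefix>_truth.tsv`).
#' Byte-identical across runs with the same seed.
#'
#' @param design A [cross_design()].
#' @param config A [sim_config()].
#' @param out_prefix Path prefix for the output files.
#' @param write_vcf Also write the minimal two-sample VCF (default `FALSE`).
#' @return Named character vector of the files written, invisibly.
#' @export
generate_dataset <- function(design, config, out_prefix, write_vcf = FALSE) {
  sim <- simulate_bsa_dataset(design, config)
  files <- c(variants = paste0(out_prefix, "_variants.tsv"),
             truth = paste0(out_prefix, "_truth.tsv"))
  write_variants_tsv(sim$sites, files[["variants"]])
  truth <- as.data.frame(sim$truth)
  truth$f_mut <- sprintf("%.10g", truth$f_mut)
  truth$f_wt <- sprintf("%.10g", truth$f_wt)
  truth$r <- sprintf("%.10g", truth$r)
  utils::write.table(truth, files[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  if (write_vcf) {
    files <- c(files, vcf = paste0(out_prefix, ".vcf"))
    write_variants_vcf(sim$sites, files[["vcf"]],
                       chrom_lengths = config$chrom_lengths)
  }
  invisible(files)
}
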