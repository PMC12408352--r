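---
title: "Mapping causal mutations with delta SNP-index scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causal mutations with delta SNP-index scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The experiment the package models

Bulked-segregant analysis by sequencing (BSA-seq) maps a monogenic mutation
without genotyping individuals. An EMS-mutagenized recessive mutant is
backcrossed to its own parental line; selfing the heterozygous progeny gives
a population segregating 1 AA : 2 Aa : 1 aa at the causal locus and 3:1 in
phenotype. Two DNA pools are formed from phenotype-contrasted individuals —
a mutant-phenotype bulk (homozygous mutant at the causal locus) and a
wild-type-phenotype bulk (1 AA : 2 Aa there) — and both pools are sequenced.

At any EMS-induced SNP, the **SNP index** of a pool is the fraction of reads
carrying the mutant (ALT) allele,

$$\mathrm{index} = \frac{n_\mathrm{alt}}{n_\mathrm{ref} + n_\mathrm{alt}},$$

and the **delta SNP index** is the mutant-pool index minus the
wild-type-pool index. At an unlinked locus both pools sample the same 1/2
allele frequency and the delta is centred on zero. At the causal locus the
mutant bulk is fixed (index 1) while the wild-type bulk averages 1/3
(enumerating the 1 AA : 2 Aa class: $(0\cdot1 + 1\cdot2)/(2\cdot3)$), so the
expected delta rises to $2/3$, decaying with recombination fraction $r$ as
$\tfrac{2}{3}(1-2r)$ along the chromosome.

Because the per-site statistic is noisy, the scan averages it in sliding
windows (25 kb advanced by 5 kb by default), flags windows against
Monte-Carlo confidence bands built under the no-linkage null, merges
significant windows into candidate regions, and intersects those with gene
annotation. A chi-square goodness-of-fit test of the phenotype counts
against 3:1 supports the single-recessive-gene model that the whole design
assumes.

## Statistical model of the null bands

A window is called significant when its mean delta falls outside an
empirical band obtained by simulating the no-linkage null at that window's
observed read depths (`simulate_null_window()`):

1. one bulk allele frequency per pool per replicate,
   $f = X/(2N)$ with $X \sim \mathrm{Binomial}(2N, \tfrac12)$, where $N$ is
   the number of lines in the bulk (44 and 50 by default). The draw is
   shared across the sites of a window: a 25-kb window is far below one
   centimorgan, so its sites are effectively completely linked, and
   independent per-site draws would understate the null variance of the
   window mean;
2. per site, an alt-read count $\mathrm{Binomial}(d, f)$ at the observed
   depth $d$ of that pool;
3. the per-site deltas are averaged and the replicate's window mean kept.

Band endpoints are nearest-rank empirical quantiles (the $q$-quantile is the
$\lceil qn\rceil$-th order statistic), chosen over interpolated quantiles so
the bands are reproducible bit-for-bit across platforms. The default is a
two-sided band at $\alpha = 0.01$, the single-window criterion under which
the peak is called; an upper-only variant is available for pure peak calls.
Significance is pointwise per window — no genome-wide correction — matching
how single-window peak criteria are usually quoted; windows overlap 5-fold
at the default size/step, so neighbouring calls are strongly correlated and
should be read as regions, not independent discoveries.

Binomial rather than hypergeometric sampling of the bulk composition is
exact in the infinite-gamete-pool limit and errs by $O(1/N^2)$ at these bulk
sizes. For a single site the null delta variance is approximately
$f(1-f)\left(\frac{1}{2N_m} + \frac{1}{D_m}\right) +
 f(1-f)\left(\frac{1}{2N_w} + \frac{1}{D_w}\right)$ at $f=\tfrac12$; this
closed form is used in the test suite as an independent oracle against the
Monte-Carlo path (about 0.148 at depths 30/30 with 44/50-line bulks).

## The forward simulator

`simulate_bsa_dataset()` emulates the experiment end to end so that every
stage can be tested against known truth:

* **Variants** (`place_variants()`): per-chromosome counts are
  Poisson(density × length) with uniform unique positions; with probability
  `ems_gc_to_at_fraction` a variant is a G>A or C>T transition (the EMS
  spectrum), otherwise one of the ten other substitutions. The causal site
  is always inserted.
* **Population** (`simulate_population()`): individuals draw causal
  genotypes at 1/4 : 1/2 : 1/4 and are drawn until both phenotype-selected
  bulks are filled. Marker genotypes derive from the causal genotype
  marker-by-marker (a star topology): each gamete keeps the allele in phase
  with its causal allele with probability $1-r$, with $r$ from the Haldane
  map function $r = \tfrac12(1 - e^{-2d})$ and $d$ in Morgans from physical
  distance at `cm_per_mb`. Full meioses with interference are not modelled;
  the star topology reproduces each site's marginal sampling distribution,
  which is what the scan statistic sees.
* **Reads** (`simulate_reads()`): per site and pool, depth is
  Poisson(`depth_mean`) and alt counts are binomial at
  $f(1-\varepsilon) + (1-f)\varepsilon$ with miscall rate $\varepsilon$.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `mut_bulk_size`, `wt_bulk_size` | 44, 50 | lines | the pool sizes of the mapping experiment the package models |
| window `size`, `step` | 25,000, 5,000 | bp | the published smoothing scale for this design |
| `alpha` | 0.01 | — | the single-window peak criterion |
| `variant_density` | 1/50,000 | variants/bp | rice-scale EMS load; sparse enough that windows hold ~0.5 sites, so smoothing is exercised |
| `depth_mean` | 30 | reads/site/pool | typical short-read pool depth |
| `error_rate` | 0.002 | per read | Illumina-scale miscall rate |
| `cm_per_mb` | 4 | cM/Mb | rice genome-wide average map rate |
| `ems_gc_to_at_fraction` | 0.95 | — | EMS induces predominantly G:C→A:T transitions |
| `min_depth_per_pool` | 8 | reads | common BSA-seq floor; the source protocol's exact filter is not published, so it is configuration, not doctrine |
| `min_site_quality` | 20 | phred-scaled | applied only where the input carries a quality value |

Sequencing depth and variant density of the original experiment were not
published; those defaults are stated assumptions chosen once at realistic
magnitudes, and everything is configurable.

### What the simulator does and does not emulate

It captures the components that drive the scan's sampling distribution:
Mendelian segregation with phenotype selection, linkage decay, finite bulk
size, finite and variable read depth, and miscalls. It does **not** emulate
mapping bias, indels or multi-allelic sites, variable local recombination,
non-uniform mutation density, incomplete penetrance, or the correlation of
bulk-composition noise between nearby markers (conditional on the causal
genotype, marker draws are independent). Passing tests therefore validate
the statistics under an idealised read-count model, not the upstream
alignment and variant-calling steps, which this package deliberately
consumes as finished input.

## Numerical and interface choices

* Coordinates are 1-based internally and in VCF/GFF3, 0-based half-open in
  every exported interval table (window TSV, region TSV, BED). A 1-based
  site $p$ belongs to window $[a,b)$ iff $a \le p-1 < b$.
* Window means are unweighted arithmetic means of member site deltas;
  windows anchor at coordinate 0 and final windows are clipped, not
  dropped; empty windows are reported with a missing mean and are never
  significant.
* Filters attribute each rejected site to the first failing rule
  (depth, then quality, then spectrum) and report per-rule counts.
* Multi-allelic and non-SNP VCF records are excluded, not decomposed: the
  statistic is defined for biallelic SNPs and EMS induces point mutations.
  A site lacking allele depths in either pool is dropped from both, since
  the delta needs both indices.
* Ties at the peak of a merged region break toward the smaller window
  start; the peak is the window start, not an interpolated summit, which
  honestly reflects window resolution.
* One root seed drives the simulator; band computation derives one child
  seed per window from its own seed, so results are reproducible and
  independent of evaluation order.

## Replicate sizes used by the shipped checks

The packaged checks run at sizes chosen to exercise the study's conditions
while staying cheap: the null-calibration check uses one causal-free 20-Mb
chromosome with 2,000 null replicates per window; the recovery check uses
50 replicate experiments on a 40-Mb chromosome with a central causal locus
and 500 null replicates per window; the window-averaging oracle uses 200
random site sets against a brute-force double loop.

## Known limitations

* **Peak ranking is noise-limited at sparse site density.** With ~0.5
  sites per 25-kb window, a region's peak is effectively a single site's
  delta. At depth ~30 its sampling s.d. (0.11–0.23 depending on depth) is
  comparable to the entire linkage gradient over several megabases
  ($\tfrac{2}{3}(1-2r)$ falls by only ~0.14 across 3 Mb at 4 cM/Mb). In
  replicate simulations the significant region *containing* the causal
  locus is essentially always present and its window mean sits near the
  theoretical 2/3, but the genome-wide *top-ranked* peak frequently lands
  one to a few megabases away. `scripts/acceptance.R` measures both rates
  (`causal_region_detected_rate` vs `causal_recovery_rate`). Practitioners
  should read the scan as region evidence plus fine-mapping, not as a
  single-window point estimate — which is exactly how marker-assisted
  follow-up is used in real mapping studies.
* The Monte-Carlo band assumes the fully penetrant recessive F2 null with
  frequency 1/2 in both bulks; distorted segregation or misphenotyping
  violates it.
* Pointwise significance at $\alpha=0.01$ implies up to ~1% flagged
  windows on a truly null genome by construction; users scanning many
  chromosomes who need genome-wide control should treat isolated
  single-window regions with suspicion. Because read counts are discrete
  and the flag uses strict inequalities against nearest-rank band
  endpoints, the realised null flag rate runs somewhat below the nominal
  $\alpha$ (conservative, never anti-conservative).
```{r}
cfg <- sim_config(c(chr1 = 2e6), seed = 1)
des <- cross_design(causal_chrom = "chr1", causal_pos = 1e6)
sim <- simulate_bsa_dataset(des, cfg)
scan <- run_bsa_scan(sim$sites, cfg$chrom_lengths, design = des,
                     band = band_spec(n_sims = 500, seed = 1))
head(scan$windows[scan$windows$significant, ])
```
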