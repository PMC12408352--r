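Package: bsascan
Title: Bulked-Segregant SNP-Index Scans with Monte-Carlo Null Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps causal mutations from phenotype-contrasted sequencing pools
    (bulked-segregant analysis, BSA-seq). Computes per-site SNP indices and the
    delta SNP index between a mutant-phenotype and a wild-type-phenotype pool,
    smooths them in sliding windows, builds Monte-Carlo confidence bands for
    the windowed statistic under the no-linkage null, merges significant
    windows into candidate regions and overlaps them with gene annotations,
    and tests Mendelian segregation ratios by chi-square. Includes a forward
    simulator of an EMS-mutagenized backcross-derived F2 experiment (3:1
    segregation, recessive-phenotype bulks, Poisson depth and binomial allele
    sampling) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
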