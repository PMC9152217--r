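Package: sexhap
Title: Pooled-Sequencing Sex Scans and Duplication-Based Y Haplotype
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate (or reject) a duplication-based Y
    sex-determining region from two complementary lines of evidence: a
    pooled male/female genome scan for sex-patterned SNPs (per-site pool
    allele frequencies, pool-Fst, a fixed-versus-intermediate filter and
    windowed summaries), and reference-guided reconstruction of an
    expected Y haplotype from duplication/deletion breakpoints, with
    classification of long noisy reads as Y-specific via a diagnostic
    deletion and backbone consensus calling with IUPAC ambiguity codes.
    A synthetic-data module generates reference haplotypes, structural
    variants, pooled allele counts and error-modelled long reads with
    full ground truth, so every stage can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
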