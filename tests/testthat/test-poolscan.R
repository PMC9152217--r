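# pool-scan: frequencies, Fst, filter, windows, and the brute-force oracle

test_that("allele frequencies drop low-count alleles as sequencing error", {
  a <- allele_frequencies(c(A = 18, G = 1, T = 1), min_read_count = 2)
  expect_equal(a$freqs, c(A = 1))
  expect_equal(a$depth, 18)

  b <- allele_frequencies(c(A = 10, T = 10), min_read_count = 2)
  expect_equal(unname(b$freqs[c("A", "T")]), c(0.5, 0.5))
  expect_equal(b$depth, 20)

  d <- allele_frequencies(c(A = 1, T = 1), min_read_count = 2)
  expect_false(d$usable)
})

test_that("site Fst reproduces the closed-form cases", {
  expect_equal(site_fst(c(A = 20), c(T = 20)), 1)
  expect_equal(site_fst(c(A = 10, T = 10), c(A = 10, T = 10)), 0)
  # pi1 = 0, pi2 = 0.5, within 0.25; pooled p(A) = 0.75 so pi_t = 0.375
  expect_equal(site_fst(c(A = 20), c(A = 10, T = 10)), 1 / 3)
  expect_true(is.na(site_fst(c(A = 1), c(A = 20))))
})

test_that("the sex filter requires one fixed pool and the same allele intermediate", {
  cfg <- scan_config()
  xy <- sex_snp_filter(c(A = 1), c(A = 0.5, T = 0.5), 20, 20, cfg)
  expect_true(xy$candidate)

  both <- sex_snp_filter(c(A = 0.95, T = 0.05), c(A = 0.95, T = 0.05),
                         20, 20, cfg)
  expect_false(both$candidate)
  expect_equal(both$reason, "both_fixed")

  dp <- sex_snp_filter(c(A = 1), c(A = 0.5, T = 0.5), 8, 50, cfg)
  expect_false(dp$candidate)
  expect_equal(dp$reason, "depth")

  # the checked frequency is of the allele fixed in the other pool
  cross <- sex_snp_filter(c(A = 1), c(T = 0.6, G = 0.4), 20, 20, cfg)
  expect_false(cross$candidate)
})

test_that("windows are anchored at 1 and count candidates under the stated convention", {
  rec <- tibble::tibble(chrom = "c", pos = c(1000L, 5000L, 12000L),
                        fst = c(1, 1, 1), candidate = TRUE, reason = "pass")
  w <- window_summary(rec, 10000)
  expect_equal(w$win_start, c(1L, 10001L))
  expect_equal(w$n_candidates, c(2L, 1L))

  rec$candidate <- FALSE
  expect_true(all(window_summary(rec, 10000)$n_candidates == 0))
  expect_equal(nrow(window_summary(rec[0, ], 10000)), 0)
})

test_that("scan output equals a brute-force recomputation on small tables", {
  ref <- fixture_ref(seed = 61, length = 25000,
                     genes = default_gene_models("desk")[0, ])
  cfg_sim <- pool_sim_config(depth_mean = 60, seq_error = 0.01,
                             snp_density = 2, sex_system = "XY",
                             sexlinked_snp_density = 2,
                             subsample_fraction = 1, seed = 13)
  sim <- simulate_pool_counts(ref, cfg_sim, sex_region = c(5001, 15000))
  counts <- head(sim$counts, 50)
  cfg <- scan_config()
  got <- scan_sex_snps(counts, cfg)$sites
  want <- brute_force_scan(counts, cfg)
  expect_equal(got$pos, want$pos)
  expect_equal(got$fst, want$fst, tolerance = 1e-12)
  expect_equal(got$candidate, want$candidate)
  expect_equal(got$reason != "unusable", want$usable)
})

test_that("fst stays in [0, 1] and the filter is monotone in its thresholds", {
  ref <- fixture_ref(seed = 62, length = 30000,
                     genes = default_gene_models("desk")[0, ])
  sim <- simulate_pool_counts(
    ref, pool_sim_config(depth_mean = 50, seq_error = 0.01, snp_density = 3,
                         sex_system = "none", subsample_fraction = 1,
                         seed = 17))
  base <- scan_sex_snps(sim$counts, scan_config())
  ok <- !is.na(base$sites$fst)
  expect_true(all(base$sites$fst[ok] >= -1e-12 & base$sites$fst[ok] <= 1))

  stricter <- scan_sex_snps(sim$counts, scan_config(fixed_threshold = 0.97))
  expect_true(all(base$sites$candidate | !stricter$sites$candidate))

  wider <- scan_sex_snps(sim$counts,
                         scan_config(min_polymorphic_freq = 0.2,
                                     max_polymorphic_freq = 0.8))
  expect_true(all(wider$sites$candidate | !base$sites$candidate))
})

test_that("a fully sex-linked site passes the filter with probability near 1", {
  # 500 replicate sex-linked sites, error-free pools of 10 at depth 100
  ref <- fixture_ref(seed = 63, length = 100000,
                     genes = default_gene_models("desk")[0, ])
  cfg_sim <- pool_sim_config(n_per_sex = 10, depth_mean = 100, seq_error = 0,
                             snp_density = 0, sexlinked_snp_density = 5,
                             subsample_fraction = 1, seed = 19)
  sim <- simulate_pool_counts(ref, cfg_sim, sex_region = c(1, 100000))
  expect_gte(nrow(sim$counts), 490)
  scan <- scan_sex_snps(sim$counts, scan_config())
  depth_ok <- scan$sites$reason != "depth"
  expect_gte(sum(depth_ok), 100)
  expect_gte(mean(scan$sites$candidate[depth_ok]), 0.995)
})

test_that("a planted XY region is recovered as the top window; a null is not enriched", {
  rep <- run_pipeline("koka-like", seed = 303)
  w <- rep$scan$windows
  top <- w$win_start[which.max(w$n_candidates)]
  dup <- default_y_spec("desk")$dup_source
  expect_true(top >= dup[1] - 2000 && top <= dup[2])
  expect_gte(nrow(rep$enriched_windows), 1)
  expect_true(all(rep$enriched_windows$win_start >= dup[1] - 2000 &
                    rep$enriched_windows$win_start <= dup[2]))

  null <- run_pipeline("hora-like", seed = 303)
  expect_equal(nrow(null$enriched_windows), 0)
})

test_that("an empty table gives empty scan output", {
  sc <- scan_sex_snps(counts_row(c(A = 10), c(A = 10))[0, ])
  expect_equal(nrow(sc$sites), 0)
  expect_equal(nrow(sc$windows), 0)
})
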