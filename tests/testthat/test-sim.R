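# synthetic-data generator: references, true Y, pooled counts, long reads

test_that("generate_reference builds seeded sequences with the requested composition", {
  r <- generate_reference(1000, gc = 0.5, seed = 1)
  expect_equal(nchar(r$seq), 1000)
  expect_true(grepl("^[ACGT]+$", r$seq))
  gc <- sum(strsplit(r$seq, "")[[1]] %in% c("G", "C")) / 1000
  expect_lt(abs(gc - 0.5), 0.06)

  r1 <- generate_reference(500, seed = 7)
  r2 <- generate_reference(500, seed = 7)
  expect_identical(r1$seq, r2$seq)
  expect_false(identical(r1$seq, generate_reference(500, seed = 8)$seq))
})

test_that("gene annotations are emitted in genomic order and overlap is rejected", {
  genes <- dplyr::bind_rows(gene_model("dot1l", 1001, 4000),
                            gene_model("oaz1", 6001, 8000),
                            gene_model("amh", 10001, 12000))
  r <- generate_reference(20000, genes, seed = 3)
  ann <- annotation_table(r)
  g <- ann[ann$type == "gene", ]
  expect_equal(g$name, c("dot1l", "oaz1", "amh"))
  expect_true(all(diff(g$start) > 0))

  bad <- dplyr::bind_rows(gene_model("a", 100, 500), gene_model("b", 400, 900))
  expect_error(generate_reference(1000, bad, seed = 1), "overlapping genes")
})

test_that("make_true_y applies every edit and does the length arithmetic", {
  x <- generate_reference(20000, seed = 2)
  spec <- y_variant_spec(dup_source = c(5001, 15000),
                         deletions = tibble::tibble(start = 7001, end = 13000))
  y <- make_true_y(x, spec)
  expect_equal(nchar(y$y_seq), 20000 + 10000 - 6000)

  expect_identical(make_true_y(x, y_variant_spec())$y_seq, x$seq)

  spec2 <- y_variant_spec(dup_source = c(5001, 10000),
                          diagnostic_deletion = c(6001, 6275))
  expect_equal(nchar(make_true_y(x, spec2)$y_seq), 20000 + 5000 - 275)

  expect_error(make_true_y(x, y_variant_spec(dup_source = c(19000, 25000))),
               "outside")
})

test_that("truth map covers every Y base and round-trips to the X", {
  fx <- fixture_desk()
  cm <- fx$truey$coord_map
  expect_equal(cm$y_start[1], 1)
  expect_equal(max(cm$y_end), nchar(fx$truey$y_seq))
  expect_true(all(cm$y_start[-1] == cm$y_end[-nrow(cm)] + 1))
  # original segments reassemble the X exactly
  orig <- cm[cm$tag == "original", ]
  expect_identical(paste(substring(fx$truey$y_seq, orig$y_start, orig$y_end),
                         collapse = ""), fx$ref$seq)
  # duplicate segments match the X source wherever no SNV was planted
  dupseg <- cm[cm$tag == "duplicate", ]
  for (i in seq_len(nrow(dupseg)))
    expect_identical(substr(fx$truey$y_seq, dupseg$y_start[i], dupseg$y_end[i]),
                     substr(fx$ref$seq, dupseg$x_start[i], dupseg$x_end[i]))
})

test_that("pooled counts conserve depth and obey the XY expectation", {
  ref <- fixture_ref(seed = 21, length = 100000,
                     genes = default_gene_models("desk")[0, ])
  cfg <- pool_sim_config(n_per_sex = 10, depth_mean = 100, seq_error = 0,
                         snp_density = 0, sexlinked_snp_density = 5,
                         subsample_fraction = 1, seed = 5)
  sim <- simulate_pool_counts(ref, cfg, sex_region = c(1, 100000))
  expect_gt(nrow(sim$counts), 400)
  expect_true(all(sim$truth$sex_linked))
  base_cols <- function(p) paste0(p, "_", c("A", "C", "G", "T"))
  d1 <- rowSums(sim$counts[, base_cols("pool1")])
  d2 <- rowSums(sim$counts[, base_cols("pool2")])
  expect_true(all(d1 >= 0) && all(d2 >= 0))
  # female pool fixed for X allele; male pool ~50% Y allele
  alt_idx <- match(sim$truth$alt, c("A", "C", "G", "T"))
  m2 <- as.matrix(sim$counts[, base_cols("pool2")])
  alt2 <- m2[cbind(seq_len(nrow(m2)), alt_idx)]
  m1 <- as.matrix(sim$counts[, base_cols("pool1")])
  alt1 <- m1[cbind(seq_len(nrow(m1)), alt_idx)]
  expect_equal(sum(alt1), 0) # no sequencing error, no Y allele in females
  expect_lt(abs(mean(alt2 / d2) - 0.5), 0.02)
})

test_that("subsampling thins realised depth proportionally", {
  ref <- fixture_ref(seed = 22, length = 50000,
                     genes = default_gene_models("desk")[0, ])
  cfg <- pool_sim_config(depth_mean = 170, seq_error = 0, snp_density = 2,
                         sex_system = "none", subsample_fraction = 0.2,
                         seed = 9)
  sim <- simulate_pool_counts(ref, cfg)
  d <- rowSums(sim$counts[, paste0("pool1_", c("A", "C", "G", "T"))])
  expect_lt(abs(mean(d) - 0.2 * 170), 2.5)
})

test_that("error-free long reads are exact substrings; n = 0 is allowed", {
  ref <- fixture_ref(seed = 31)
  m0 <- long_read_error_model(error_rate = 0, length_meanlog = log(3000),
                              length_sdlog = 0.3, seed = 4)
  sim <- simulate_long_reads(ref, 20, m0, origin = "X")
  expect_equal(nrow(sim$reads), 20)
  for (i in seq_len(20))
    expect_identical(sim$reads$seq[i],
                     substr(ref$seq, sim$truth$start[i], sim$truth$end[i]))
  # truth completeness: every read id exactly once
  expect_setequal(sim$reads$read_id, sim$truth$read_id)
  expect_equal(anyDuplicated(sim$truth$read_id), 0)

  empty <- simulate_long_reads(ref, 0, m0)
  expect_equal(nrow(empty$reads), 0)
})

test_that("seeded simulation is deterministic end to end", {
  ref <- fixture_ref(seed = 41)
  m <- long_read_error_model(seed = 6, length_meanlog = log(2000))
  s1 <- simulate_long_reads(ref, 10, m)
  s2 <- simulate_long_reads(ref, 10, m)
  expect_identical(s1$reads, s2$reads)
  cfg <- pool_sim_config(seed = 7, sex_system = "none")
  p1 <- simulate_pool_counts(ref, cfg)
  p2 <- simulate_pool_counts(ref, cfg)
  expect_identical(p1$counts, p2$counts)
})

test_that("injected long-read error matches the configured rate", {
  ref <- fixture_ref(seed = 51, length = 20000,
                     genes = default_gene_models("desk")[0, ])
  m <- long_read_error_model(length_meanlog = log(8000), length_sdlog = 0.05,
                             seed = 8)
  sim <- simulate_long_reads(ref, 40, m)
  errs <- vapply(seq_len(40), function(i) {
    a <- align_to_target(sim$reads$seq[i], ref$seq)
    (a$nmismatch + a$nins + a$ndel) / (a$nmatch + a$nmismatch + a$ndel)
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.0644), 0.004)
})
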