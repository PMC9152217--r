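# bait preparation/filtering, trimming, alignment, diagnostic classification

test_that("bait segments follow the masking rules", {
  genes <- dplyr::bind_rows(
    gene_model("dot1l", 1001, 4000,
               masked = tibble::tibble(start = 1501, end = 2500)),
    gene_model("oaz1", 5001, 6000),
    gene_model("amh", 7001, 8000))
  ref <- generate_reference(10000, genes, seed = 81)
  baits <- prepare_baits(genes, ref)
  expect_equal(sum(baits$gene == "dot1l"), 2) # intron mask splits the gene
  expect_equal(sum(baits$gene == "oaz1"), 1)
  expect_equal(sum(baits$gene == "amh"), 1)

  full_mask <- gene_model("gone", 9001, 9500,
                          masked = tibble::tibble(start = 9001, end = 9500))
  expect_warning(b2 <- prepare_baits(dplyr::bind_rows(genes, full_mask), ref),
                 "fully masked")
  expect_false("gone" %in% b2$gene)
})

test_that("bait filter keeps locus reads and rejects unrelated sequence", {
  genes <- default_gene_models("desk")
  ref <- fixture_ref(seed = 82)
  baits <- prepare_baits(genes, ref)

  amh <- genes[genes$name == "amh", ]
  read_with_bait <- substr(ref$seq, amh$start, amh$end)
  kept <- bait_filter(tibble::tibble(read_id = "r1", seq = read_with_bait),
                      baits)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$bait_hit, "amh")

  # composition-matched random reads: false-positive rate under 1%
  rand <- local({
    set.seed(83)
    tibble::tibble(read_id = sprintf("n%03d", 1:100),
                   seq = replicate(100, sexhap:::random_dna(2000, gc = 0.41)))
  })
  expect_lt(nrow(bait_filter(rand, baits)) / 100, 0.01)
})

test_that("a junction read with only a partial bait overlap is retained", {
  fx <- fixture_desk(seed = 84)
  genes <- default_gene_models("desk")
  baits <- prepare_baits(genes, fx$ref)
  # true-Y read crossing from just inside oaz1 into downstream sequence
  oaz <- genes[genes$name == "oaz1", ]
  cm <- fx$truey$coord_map
  dupseg <- cm[cm$tag == "duplicate", ]
  y_of_x <- function(xp) {
    seg <- dupseg[dupseg$x_start <= xp & dupseg$x_end >= xp, ][1, ]
    seg$y_start + (xp - seg$x_start)
  }
  j <- y_of_x(oaz$end - 150) # 150 bp of oaz1 copy at the read 5' end
  read <- substr(fx$truey$y_seq, j, j + 2500)
  kept <- bait_filter(tibble::tibble(read_id = "jx", seq = read), baits,
                      min_hit_score = 60)
  expect_equal(nrow(kept), 1)
})

test_that("end trimming removes 23 bp per side and drops too-short reads", {
  expect_equal(nchar(trim_ends(strrep("A", 100))), 54)
  expect_message(out <- trim_ends(c(strrep("A", 46), strrep("A", 100))),
                 "dropped")
  expect_equal(length(out), 1)
  expect_identical(trim_ends("ACGTACGT", n = 0), "ACGTACGT")
})

test_that("alignment recovers exact substrings and survives 6.44% error", {
  ref <- fixture_ref(seed = 85)
  a <- align_to_target(substr(ref$seq, 4001, 9000), ref$seq)
  expect_true(a$aligned)
  expect_equal(c(a$tstart, a$tend), c(4001, 9000))
  expect_equal(a$identity, 1)

  m <- long_read_error_model(length_meanlog = log(5000), length_sdlog = 0.05,
                             seed = 86)
  sim <- simulate_long_reads(ref, 15, m)
  ids <- vapply(seq_len(15), function(i) {
    al <- align_to_target(sim$reads$seq[i], ref$seq)
    expect_lt(abs(al$tstart - sim$truth$start[i]), 10)
    al$identity
  }, numeric(1))
  expect_lt(abs(mean(ids) - 0.94), 0.02)

  expect_false(align_to_target(sexhap:::random_dna(3000), ref$seq)$aligned)
})

test_that("classification detects the diagnostic deletion exactly at zero error", {
  fx <- fixture_desk(seed = 87)
  dd <- fx$spec$diagnostic_deletion
  diag <- list(start = dd[1], end = dd[2], expected_length = dd[2] - dd[1] + 1)
  cm <- fx$truey$coord_map
  dupseg <- cm[cm$tag == "duplicate", ]
  j <- max(dupseg$y_start[dupseg$x_start <= dd[1]] +
             (dd[1] - dupseg$x_start[dupseg$x_start <= dd[1]])) - 1

  y_read <- substr(fx$truey$y_seq, j - 1500, j + 1500)
  cy <- classify_read(y_read, fx$ref$seq, diag)
  expect_equal(cy$label, "Y-specific")
  expect_equal(cy$observed_length, 275L)
  expect_true(cy$spans_locus)

  x_read <- substr(fx$ref$seq, dd[1] - 1500, dd[2] + 1500)
  cx <- classify_read(x_read, fx$ref$seq, diag)
  expect_equal(cx$label, "non-Y")
  expect_false(cx$deletion_detected)

  short <- substr(fx$truey$y_seq, j - 2000, j - 50) # ends before the locus
  cs <- classify_read(short, fx$ref$seq, diag)
  expect_equal(cs$label, "unassigned")
})

test_that("every retained read gets exactly one label and the tally reconciles", {
  fx <- fixture_desk(seed = 88)
  genes <- default_gene_models("desk")
  baits <- prepare_baits(genes, fx$ref)
  m <- long_read_error_model(error_rate = 0, length_meanlog = log(4000),
                             length_sdlog = 0.1, seed = 89)
  rx <- simulate_long_reads(fx$ref, 10, m, origin = "X", id_prefix = "rx")
  ry <- simulate_long_reads(fx$truey, 10, m, origin = "Y", id_prefix = "ry")
  reads <- dplyr::bind_rows(rx$reads, ry$reads)
  cl <- classify_reads(reads, fx$ref, fx$spec, baits = baits)
  expect_equal(nrow(cl$calls), cl$n_bait_pass - cl$n_trimmed_out)
  expect_true(all(cl$calls$label %in% c("Y-specific", "non-Y", "unassigned")))
  expect_equal(sum(cl$labels), nrow(cl$calls))
  # label invariants
  ys <- cl$calls[cl$calls$label == "Y-specific", ]
  expect_true(all(ys$deletion_detected))
  ny <- cl$calls[cl$calls$label == "non-Y", ]
  expect_true(all(ny$spans_locus & !ny$deletion_detected))
  # exactness at zero error: no X-origin read is ever Y-specific
  expect_false(any(grepl("^rx", ys$read_id)))
})

test_that("classification is concordant with the truth at 6.44% error", {
  fx <- fixture_desk(seed = 90)
  dd <- fx$spec$diagnostic_deletion
  diag <- list(start = dd[1], end = dd[2], expected_length = 275)
  # only reads crossing the diagnostic junction inside the duplicated copy
  # carry the deletion; Y-origin reads from the conserved regions are
  # genuinely "non-Y" by the diagnostic, exactly like X reads
  cm <- fx$truey$coord_map
  dupseg <- cm[cm$tag == "duplicate", ]
  j <- dupseg$y_end[dupseg$x_end == dd[1] - 1] # last Y base before the gap
  m <- long_read_error_model(length_meanlog = log(6000), length_sdlog = 0.05,
                             seed = 91)
  rx <- simulate_long_reads(fx$ref, 20, m, origin = "X", id_prefix = "rx")
  ry <- simulate_long_reads(fx$truey, 20, m, origin = "Y", id_prefix = "ry")
  classify <- function(sim) {
    out <- purrr::map_dfr(sim$reads$seq, classify_read, fx$ref$seq, diag,
                          flank = 200, tol = 30)
    dplyr::bind_cols(out, sim$truth)
  }
  calls <- dplyr::bind_rows(classify(rx), classify(ry))
  crosses <- calls$origin == "Y" & calls$start <= j - 300 &
    calls$end >= j + 300
  spanning <- calls[calls$spans_locus, ]
  expect_gte(nrow(spanning), 8)
  want <- ifelse(crosses[calls$spans_locus], "Y-specific", "non-Y")
  expect_gte(mean(spanning$label == want), 0.95)
  # and every junction-crossing read is recovered
  expect_gte(sum(crosses), 3)
  expect_gte(mean(calls$label[crosses] == "Y-specific"), 0.95)
})

test_that("classification of a read ignores the rest of the batch", {
  fx <- fixture_desk(seed = 92)
  m <- long_read_error_model(length_meanlog = log(4000), seed = 93)
  sim <- simulate_long_reads(fx$truey, 6, m, origin = "Y")
  alone <- classify_reads(sim$reads[3, ], fx$ref, fx$spec, trim = 23)
  batch <- classify_reads(sim$reads, fx$ref, fx$spec, trim = 23)
  expect_equal(alone$calls$label,
               batch$calls$label[batch$calls$read_id ==
                                   sim$reads$read_id[3]])
})

test_that("the banded aligner agrees with a classical global aligner on toys", {
  skip_if_not_installed("Biostrings")
  set.seed(94)
  for (i in 1:5) {
    t <- sexhap:::random_dna(600)
    # mutate a copy lightly
    q <- sexhap:::inject_read_errors(
      substr(t, 51, 550),
      long_read_error_model(error_rate = 0.05, seed = 94 + i))
    ours <- align_to_target(q, t, band_pad = 100, min_chain_score = 20)
    ref_aln <- Biostrings::pairwiseAlignment(
      q, t, type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -4, baseOnly = TRUE),
      gapOpening = 4, gapExtension = 2)
    expect_true(ours$aligned)
    # same optimal score, and edit statistics agree
    expect_equal(ours$score, Biostrings::score(ref_aln))
    expect_equal(ours$nmatch,
                 Biostrings::nmatch(ref_aln))
  }
})
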