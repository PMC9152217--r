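# expected-Y construction, annotation liftover, region extraction, coord map

test_that("duplication and deletion size classes follow the reconstruction rule", {
  x <- generate_reference(1000, seed = 71)
  spec <- y_variant_spec(dup_source = c(301, 500), dup_insert_at = 601)
  m <- build_expected_y(x, spec = spec)
  expect_equal(nchar(m$y_seq), 1200)

  # a 50 bp deletion is below the keep threshold: sequence retained
  spec2 <- y_variant_spec(dup_source = c(301, 500), dup_insert_at = 601,
                          deletions = tibble::tibble(start = 351, end = 400))
  m2 <- build_expected_y(x, spec = spec2)
  expect_equal(nchar(m2$y_seq), 1200)
  expect_false(m2$deletions$applied[1])

  # a >= 5 kb deletion is applied
  x3 <- generate_reference(20000, seed = 72)
  spec3 <- y_variant_spec(dup_source = c(5001, 15000),
                          deletions = tibble::tibble(start = 6001, end = 12000))
  m3 <- build_expected_y(x3, spec = spec3)
  expect_equal(nchar(m3$y_seq), 20000 + 10000 - 6000)

  # the diagnostic deletion is always applied despite being small
  spec4 <- y_variant_spec(dup_source = c(5001, 15000),
                          diagnostic_deletion = c(7001, 7275))
  expect_equal(nchar(build_expected_y(x3, spec = spec4)$y_seq),
               20000 + 10000 - 275)
})

test_that("mid-size deletions demand an explicit override", {
  x <- generate_reference(20000, seed = 73)
  spec <- y_variant_spec(dup_source = c(5001, 15000),
                         deletions = tibble::tibble(start = 6001, end = 8000))
  expect_error(build_expected_y(x, spec = spec), "explicit")

  forced <- y_variant_spec(dup_source = c(5001, 15000),
                           deletions = tibble::tibble(start = 6001, end = 8000,
                                                      apply = TRUE))
  expect_equal(nchar(build_expected_y(x, spec = forced)$y_seq),
               20000 + 10000 - 2000)
  kept <- y_variant_spec(dup_source = c(5001, 15000),
                         deletions = tibble::tibble(start = 6001, end = 8000,
                                                    apply = FALSE))
  expect_equal(nchar(build_expected_y(x, spec = kept)$y_seq), 30000)
})

test_that("length bookkeeping is exact for the default layouts", {
  for (scale in c("desk", "full")) {
    genes <- default_gene_models(scale)
    spec <- default_y_spec(scale)
    ref <- generate_reference(default_region_length(scale), genes, seed = 74)
    m <- build_expected_y(ref, spec = spec)
    dup_len <- spec$dup_source[2] - spec$dup_source[1] + 1
    applied <- sum(m$deletions$length[m$deletions$applied])
    ins_len <- sum(nchar(spec$insertions$seq))
    expect_equal(nchar(m$y_seq),
                 nchar(ref$seq) + dup_len - applied + ins_len)
    # the true Y additionally applies the kept deletions
    ty <- make_true_y(ref, spec)
    expect_equal(nchar(ty$y_seq),
                 nchar(ref$seq) + dup_len - sum(m$deletions$length) + ins_len)
  }
})

test_that("the edit script is reversible: original segments rebuild the X", {
  fx <- fixture_desk(seed = 75)
  for (obj in list(fx$model, fx$truey)) {
    orig <- obj$coord_map[obj$coord_map$tag == "original", ]
    expect_identical(
      paste(substring(obj$y_seq, orig$y_start, orig$y_end), collapse = ""),
      fx$ref$seq)
  }
})

test_that("liftover duplicates features, flags truncations, names chimeras", {
  genes <- dplyr::bind_rows(gene_model("oaz1", 5101, 6000),
                            gene_model("amh", 7001, 8000))
  ref <- generate_reference(20000, genes, seed = 76)
  spec <- y_variant_spec(dup_source = c(5001, 10000))
  ann <- liftover_annotations(build_expected_y(ref, spec = spec))
  expect_setequal(ann$name, c("oaz1", "amh", "oaz1_dup", "amh_dup"))
  expect_true(all(ann$flag == "ok"))

  # a large deletion spanning the end of gene A and the start of gene B
  # (and the whole gap) fuses the copies into one chimera
  spec2 <- y_variant_spec(dup_source = c(5001, 12000),
                          deletions = tibble::tibble(start = 5800, end = 11000,
                                                     apply = TRUE))
  genes2 <- dplyr::bind_rows(gene_model("dot1l", 5101, 6000),
                             gene_model("oaz1", 10500, 11800))
  ann2 <- liftover_annotations(
    build_expected_y(generate_reference(20000, genes2, seed = 77),
                     genes2, spec2))
  expect_true("dot1l-oaz1_chimera" %in% ann2$name)
  expect_false(any(c("dot1l_dup", "oaz1_dup") %in% ann2$name))

  # empty spec: annotations identical to the X
  ann3 <- liftover_annotations(build_expected_y(ref, genes,
                                                y_variant_spec()))
  expect_equal(ann3$name, genes$name)
  expect_equal(ann3$start, genes$start)
})

test_that("liftover is idempotent (same model, same output)", {
  fx <- fixture_desk(seed = 78)
  m <- build_expected_y(fx$ref, spec = fx$spec)
  expect_identical(liftover_annotations(m), liftover_annotations(m))
})

test_that("extract_region slices 1-based inclusive coordinates", {
  s <- "ABCDEFGHIJKLMNOPQRSTUVWXYZQRST"
  expect_identical(extract_region(s, 1, nchar(s)), s)
  expect_identical(extract_region(s, 5, 5), "E")
  expect_identical(extract_region(s, 11, 20), substr(s, 11, 20))
  expect_equal(nchar(extract_region(s, 11, 20)), 10)
  expect_error(extract_region(s, 0, 5), "out of bounds")
  expect_error(extract_region(s, 20, 40), "out of bounds")
})

test_that("y_to_x round-trips positions through the edit script", {
  fx <- fixture_desk(seed = 79)
  m <- fx$model
  ins_at <- fx$spec$dup_insert_at
  # before the insertion point: identity, tag original
  before <- y_to_x(m, c(1, ins_at - 1))
  expect_equal(before$x_pos, c(1L, ins_at - 1L))
  expect_true(all(before$tag == "original"))
  # inside the duplicate copy: x position within dup_source, tag duplicate
  dupseg <- m$coord_map[m$coord_map$tag == "duplicate", ]
  mid <- y_to_x(m, dupseg$y_start[1] + 5)
  expect_equal(mid$tag, "duplicate")
  expect_equal(mid$x_pos, dupseg$x_start[1] + 5L)
  expect_identical(substr(m$y_seq, mid$y_pos, mid$y_pos),
                   substr(fx$ref$seq, mid$x_pos, mid$x_pos))
  # inside the planted insertion: gap
  insseg <- m$coord_map[m$coord_map$tag == "insertion", ]
  expect_true(nrow(insseg) >= 1)
  expect_true(is.na(y_to_x(m, insseg$y_start[1])$x_pos))
  expect_error(y_to_x(m, nchar(m$y_seq) + 1), "out of range")
})
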