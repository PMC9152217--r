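# fixtures built in code; everything is seeded and small

fixture_ref <- function(seed = 11, length = 20000,
                        genes = default_gene_models("desk")) {
  generate_reference(length, genes, seed = seed)
}

fixture_desk <- function(seed = 11) {
  ref <- fixture_ref(seed)
  spec <- default_y_spec("desk")
  list(ref = ref, spec = spec,
       model = build_expected_y(ref, spec = spec),
       truey = make_true_y(ref, spec))
}

# independent brute-force recomputation of the scan, written without the
# package's vectorised path: per-site loops over plain lists
brute_force_scan <- function(counts, cfg) {
  out <- list()
  for (i in seq_len(nrow(counts))) {
    c1 <- c(A = counts$pool1_A[i], C = counts$pool1_C[i],
            G = counts$pool1_G[i], T = counts$pool1_T[i])
    c2 <- c(A = counts$pool2_A[i], C = counts$pool2_C[i],
            G = counts$pool2_G[i], T = counts$pool2_T[i])
    k1 <- c1[c1 >= cfg$min_read_count]
    k2 <- c2[c2 >= cfg$min_read_count]
    d1 <- sum(k1); d2 <- sum(k2)
    usable <- d1 > 0 && d2 > 0
    fst <- NA_real_
    cand <- FALSE
    if (usable) {
      p1 <- k1 / d1; p2 <- k2 / d2
      pi1 <- 1 - sum(p1^2); pi2 <- 1 - sum(p2^2)
      tot <- c(A = 0, C = 0, G = 0, T = 0)
      tot[names(k1)] <- tot[names(k1)] + k1
      tot[names(k2)] <- tot[names(k2)] + k2
      pt <- 1 - sum((tot / sum(tot))^2)
      fst <- if (pt == 0) 0 else max(0, (pt - (pi1 + pi2) / 2) / pt)
      depth_ok <- d1 >= cfg$min_depth && d1 <= cfg$max_depth &&
        d2 >= cfg$min_depth && d2 <= cfg$max_depth
      test_dir <- function(pa, pb) {
        if (length(pa) == 0) return(FALSE)
        a <- names(pa)[which.max(pa)]
        if (pa[[a]] < cfg$fixed_threshold) return(FALSE)
        f <- if (a %in% names(pb)) pb[[a]] else 0
        f >= cfg$min_polymorphic_freq && f <= cfg$max_polymorphic_freq
      }
      cand <- depth_ok && (test_dir(p1, p2) || test_dir(p2, p1))
    }
    out[[i]] <- data.frame(pos = counts$pos[i], fst = fst,
                           candidate = cand, usable = usable)
  }
  do.call(rbind, out)
}

# one-row pooled-counts tibble from two named count vectors
counts_row <- function(c1, c2, pos = 1, chrom = "chrT", ref = "A") {
  row <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref)
  for (b in c("A", "C", "G", "T")) {
    row[[paste0("pool1_", b)]] <- as.integer(c1[b] %|0|% 0)
    row[[paste0("pool2_", b)]] <- as.integer(c2[b] %|0|% 0)
  }
  for (p in c("pool1", "pool2"))
    for (b in c("N", "del")) row[[paste0(p, "_", b)]] <- 0L
  row
}

`%|0|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
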