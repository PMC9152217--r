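#' Configuration for the pooled sex-SNP scan
#'
#' Defaults are the classical settings for detecting sites fixed (or nearly
#' fixed) in one sex and at intermediate frequency in the other:
#' fixed threshold 0.9, intermediate band \[0.3, 0.7\], depth window
#' \[10, 100\], minimum per-allele read count 2 and 10 kb windows.
#'
#' @param fixed_threshold major-allele frequency at/above which a pool
#'   counts as fixed.
#' @param min_polymorphic_freq,max_polymorphic_freq intermediate-frequency
#'   band required of the other pool for the fixed allele.
#' @param min_depth,max_depth usable effective depth window per pool.
#' @param min_read_count alleles with fewer reads are dropped as sequencing
#'   error before frequencies are computed.
#' @param window_size non-overlapping window size in bp, anchored at
#'   position 1.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(fixed_threshold = 0.9, min_polymorphic_freq = 0.3,
                        max_polymorphic_freq = 0.7, min_depth = 10,
                        max_depth = 100, min_read_count = 2,
                        window_size = 10000) {
  stopifnot(fixed_threshold > 0.5, fixed_threshold <= 1,
            min_polymorphic_freq < max_polymorphic_freq,
            min_polymorphic_freq >= 0, max_polymorphic_freq <= 1,
            min_depth <= max_depth, min_depth >= 0,
            min_read_count >= 0, window_size >= 1)
  structure(list(fixed_threshold = fixed_threshold,
                 min_polymorphic_freq = min_polymorphic_freq,
                 max_polymorphic_freq = max_polymorphic_freq,
                 min_depth = min_depth, max_depth = max_depth,
                 min_read_count = min_read_count, window_size = window_size),
            class = "scan_config")
}

#' Per-allele frequencies after minimum-count filtering
#'
#' Alleles supported by fewer than `min_read_count` reads are discarded as
#' sequencing error; frequencies are computed over the retained counts and
#' sum to 1. A site where no allele reaches the minimum is unusable.
#'
#' @param counts named numeric vector of per-allele read counts (names among
#'   A/C/G/T; N and del entries are ignored).
#' @param min_read_count minimum reads per retained allele.
#' @return list with `freqs` (named, over retained alleles), `depth`
#'   (sum of retained counts) and `usable`.
#' @export
allele_frequencies <- function(counts, min_read_count = 2) {
  counts <- counts[names(counts) %in% BASES]
  kept <- counts[counts >= min_read_count]
  if (length(kept) == 0 || sum(kept) == 0)
    return(list(freqs = numeric(), depth = 0, usable = FALSE))
  list(freqs = kept / sum(kept), depth = sum(kept), usable = TRUE)
}

# pi = expected heterozygosity 1 - sum p_i^2 from a count vector
pi_from_counts <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  1 - sum((counts / tot)^2)
}

#' Pool-Fst for one site from two pools' allele counts
#'
#' The classical pi-based pool estimator:
#' `fst = (pi_total - pi_within) / pi_total` with `pi = 1 - sum(p_i^2)` per
#' pool, `pi_within` the mean of the two pool values, and `pi_total`
#' computed from the summed retained counts. Identical pools give exactly 0;
#' pools fixed for different alleles give 1. `pi_total = 0` returns 0 by
#' convention. No unbiasedness correction is applied.
#'
#' @param counts1,counts2 named per-allele count vectors.
#' @param min_read_count passed to [allele_frequencies()].
#' @return Fst in \[0, 1\], or NA if either pool is unusable.
#' @export
site_fst <- function(counts1, counts2, min_read_count = 2) {
  a1 <- allele_frequencies(counts1, min_read_count)
  a2 <- allele_frequencies(counts2, min_read_count)
  if (!a1$usable || !a2$usable) return(NA_real_)
  k1 <- a1$freqs * a1$depth
  k2 <- a2$freqs * a2$depth
  alle <- union(names(k1), names(k2))
  tot <- setNames(numeric(length(alle)), alle)
  tot[names(k1)] <- tot[names(k1)] + k1
  tot[names(k2)] <- tot[names(k2)] + k2
  pi_w <- mean(c(1 - sum(a1$freqs^2), 1 - sum(a2$freqs^2)))
  pi_t <- pi_from_counts(tot)
  if (pi_t == 0) return(0)
  # unequal pool depths can push the plain estimator slightly negative;
  # truncate at 0 as sex-scan tools conventionally do
  max(0, (pi_t - pi_w) / pi_t)
}

#' Sex-pattern filter for one scanned site
#'
#' A site is a candidate when both effective depths lie within the depth
#' window and one pool is fixed (major-allele frequency at or above
#' `fixed_threshold`) while the *same* allele sits in the intermediate band
#' in the other pool - the signature of an X-linked allele fixed in the
#' homogametic sex and heterozygous in the other.
#'
#' @param freqs1,freqs2 retained allele frequencies per pool
#'   (from [allele_frequencies()]).
#' @param depth1,depth2 effective depths per pool.
#' @param cfg a [scan_config()].
#' @return list with `candidate` and `reason`
#'   ("pass"/"depth"/"both_fixed"/"not_fixed"/"not_intermediate").
#' @export
sex_snp_filter <- function(freqs1, freqs2, depth1, depth2,
                           cfg = scan_config()) {
  if (depth1 < cfg$min_depth || depth1 > cfg$max_depth ||
      depth2 < cfg$min_depth || depth2 > cfg$max_depth)
    return(list(candidate = FALSE, reason = "depth"))
  dir_ok <- function(fixed, other) {
    if (length(fixed) == 0) return(NA)
    a <- names(fixed)[which.max(fixed)]
    if (fixed[[a]] < cfg$fixed_threshold) return(NA)
    f <- if (a %in% names(other)) other[[a]] else 0
    f >= cfg$min_polymorphic_freq && f <= cfg$max_polymorphic_freq
  }
  d1 <- dir_ok(freqs1, freqs2)
  d2 <- dir_ok(freqs2, freqs1)
  if (isTRUE(d1) || isTRUE(d2))
    return(list(candidate = TRUE, reason = "pass"))
  if (is.na(d1) && is.na(d2))
    return(list(candidate = FALSE, reason = "not_fixed"))
  if (!is.na(d1) && !is.na(d2))
    return(list(candidate = FALSE, reason = "both_fixed"))
  list(candidate = FALSE, reason = "not_intermediate")
}

# vectorised scan over a counts tibble; returns the ScanRecord table
scan_records <- function(counts, cfg) {
  n <- nrow(counts)
  pool_mat <- function(prefix) {
    m <- as.matrix(counts[, paste0(prefix, "_", BASES)])
    colnames(m) <- BASES
    m
  }
  m1 <- pool_mat("pool1"); m2 <- pool_mat("pool2")
  r1 <- m1 * (m1 >= cfg$min_read_count)
  r2 <- m2 * (m2 >= cfg$min_read_count)
  depth1 <- rowSums(r1); depth2 <- rowSums(r2)
  usable <- depth1 > 0 & depth2 > 0

  f1 <- r1 / ifelse(depth1 > 0, depth1, 1)
  f2 <- r2 / ifelse(depth2 > 0, depth2, 1)

  # pool1's major allele (ties broken lexicographically: columns are A<C<G<T)
  maj1 <- max.col(f1, ties.method = "first")
  major_allele <- BASES[maj1]
  freq1 <- f1[cbind(seq_len(n), maj1)]
  freq2 <- f2[cbind(seq_len(n), maj1)]

  pi1 <- 1 - rowSums(f1^2)
  pi2 <- 1 - rowSums(f2^2)
  tot <- r1 + r2
  ft <- tot / ifelse(depth1 + depth2 > 0, depth1 + depth2, 1)
  pi_t <- 1 - rowSums(ft^2)
  fst <- pmax(0, ifelse(pi_t == 0, 0, (pi_t - (pi1 + pi2) / 2) / pi_t))
  fst[!usable] <- NA_real_

  # filter, both directions
  maj2 <- max.col(f2, ties.method = "first")
  fx1 <- freq1 >= cfg$fixed_threshold
  fx2 <- f2[cbind(seq_len(n), maj2)] >= cfg$fixed_threshold
  inter12 <- freq2 >= cfg$min_polymorphic_freq &
    freq2 <= cfg$max_polymorphic_freq
  f1_of_maj2 <- f1[cbind(seq_len(n), maj2)]
  inter21 <- f1_of_maj2 >= cfg$min_polymorphic_freq &
    f1_of_maj2 <= cfg$max_polymorphic_freq
  depth_ok <- depth1 >= cfg$min_depth & depth1 <= cfg$max_depth &
    depth2 >= cfg$min_depth & depth2 <= cfg$max_depth
  cand <- usable & depth_ok & ((fx1 & inter12) | (fx2 & inter21))

  reason <- rep("pass", n)
  reason[!(fx1 | fx2)] <- "not_fixed"
  reason[(fx1 | fx2) & !cand] <- "not_intermediate"
  reason[fx1 & fx2 & !cand] <- "both_fixed"
  reason[!depth_ok] <- "depth"
  reason[!usable] <- "unusable"
  reason[cand] <- "pass"

  tibble::tibble(chrom = counts$chrom, pos = counts$pos,
                 major_allele = major_allele,
                 freq1 = freq1, freq2 = freq2,
                 depth1 = depth1, depth2 = depth2,
                 fst = fst, candidate = cand, reason = reason)
}

#' Windowed summary of scan records
#'
#' Non-overlapping windows `[k*w + 1, (k+1)*w]` in 1-based coordinates,
#' anchored at position 1.
#'
#' @param records a ScanRecord tibble ([scan_sex_snps()] sites, or
#'   anything with `chrom`, `pos`, `fst`, `candidate`, `reason`).
#' @param window_size window size in bp.
#' @return tibble with `chrom`, `win_start`, `win_end`, `n_sites` (usable),
#'   `n_candidates`, `mean_fst`.
#' @export
window_summary <- function(records, window_size = 10000) {
  if (nrow(records) == 0)
    return(tibble::tibble(chrom = character(), win_start = integer(),
                          win_end = integer(), n_sites = integer(),
                          n_candidates = integer(), mean_fst = double()))
  records |>
    dplyr::mutate(win_start = as.integer((.data$pos - 1) %/% window_size *
                                           window_size + 1)) |>
    dplyr::group_by(.data$chrom, .data$win_start) |>
    dplyr::summarise(
      win_end = .data$win_start[1] + as.integer(window_size) - 1L,
      n_sites = sum(.data$reason != "unusable"),
      n_candidates = sum(.data$candidate),
      mean_fst = if (any(!is.na(.data$fst)))
        mean(.data$fst, na.rm = TRUE) else NA_real_,
      .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$win_start)
}

#' Run the pooled sex-SNP scan
#'
#' Computes per-site retained allele frequencies, pool-Fst, the
#' fixed-versus-intermediate candidate verdict and windowed summaries - the
#' table behind a Manhattan plot of sex differentiation.
#'
#' @param counts a pooled-counts tibble (as produced by
#'   [simulate_pool_counts()] or [read_sync()]), or a path to a sync file.
#' @param cfg a [scan_config()].
#' @return object of class `sexscan`: list with `sites` (ScanRecord tibble),
#'   `windows` ([window_summary()]), `cfg` and `n_rejected` (malformed
#'   input lines, when read from file). `tidy()` returns the site table,
#'   `glance()` a one-row summary, `autoplot()` a Manhattan plot.
#' @export
scan_sex_snps <- function(counts, cfg = scan_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  n_rejected <- 0L
  if (is.character(counts) && length(counts) == 1) {
    counts <- read_sync(counts)
    n_rejected <- attr(counts, "n_rejected") %||% 0L
  }
  if (inherits(counts, "pool_sim")) counts <- counts$counts
  if (nrow(counts) == 0) {
    sites <- scan_records(counts[0, ], cfg)
  } else {
    counts <- dplyr::arrange(counts, .data$chrom, .data$pos)
    sites <- scan_records(counts, cfg)
  }
  structure(list(sites = sites,
                 windows = window_summary(sites, cfg$window_size),
                 cfg = cfg, n_rejected = n_rejected),
            class = "sexscan")
}

#' @export
print.sexscan <- function(x, ...) {
  cat("<sexscan>", nrow(x$sites), "sites,",
      sum(x$sites$candidate), "candidates,",
      nrow(x$windows), "windows\n")
  invisible(x)
}

#' @rdname scan_sex_snps
#' @param x a `sexscan` object.
#' @param ... unused.
#' @export
tidy.sexscan <- function(x, ...) x$sites

#' @rdname scan_sex_snps
#' @export
glance.sexscan <- function(x, ...) {
  top <- enriched_windows(x)
  tibble::tibble(
    n_sites = nrow(x$sites),
    n_usable = sum(x$sites$reason != "unusable"),
    n_candidates = sum(x$sites$candidate),
    n_windows = nrow(x$windows),
    n_enriched_windows = nrow(top),
    top_window_start = if (nrow(x$windows))
      x$windows$win_start[which.max(x$windows$n_candidates)] else NA_integer_,
    top_window_candidates = if (nrow(x$windows))
      max(x$windows$n_candidates) else NA_integer_,
    n_rejected_lines = x$n_rejected)
}

#' Windows enriched for sex-pattern candidates over the empirical null
#'
#' A window counts as enriched when its candidate count exceeds the 95th
#' percentile of per-window candidate counts (the empirical null) and
#' reaches an absolute floor of co-localised candidates; isolated false
#' positives from binomial sampling noise produce 1-2 scattered candidates
#' per window, which the floor excludes.
#'
#' @param x a `sexscan` object or windows tibble.
#' @param min_candidates absolute floor for enrichment. Default 3.
#' @return the enriched subset of the windows tibble.
#' @export
enriched_windows <- function(x, min_candidates = 3) {
  w <- if (inherits(x, "sexscan")) x$windows else x
  if (nrow(w) == 0) return(w)
  null95 <- quantile(w$n_candidates, 0.95, type = 1, names = FALSE)
  w[w$n_candidates > null95 & w$n_candidates >= min_candidates, ]
}

#' Manhattan plot of per-site pool-Fst
#'
#' @param object a `sexscan` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sexscan <- function(object, ...) {
  d <- object$sites[object$sites$reason != "unusable", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$fst,
                                  colour = .data$candidate)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(F[ST]),
                  colour = "sex-pattern\ncandidate") +
    ggplot2::theme_minimal()
}
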