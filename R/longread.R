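#' Build bait segments from gene models
#'
#' Each gene contributes one bait segment per maximal unmasked run of its
#' span; a gene with one masked internal intron therefore yields exactly two
#' segments, and a fully masked gene yields none (with a warning). Masking
#' exists to remove intervals that resemble unrelated paralogs (e.g. an
#' intron shared with a *vasa*-like gene) which would otherwise recruit
#' off-target reads.
#'
#' @param genes gene-model tibble ([gene_model()] rows).
#' @param reference sequence the gene coordinates refer to.
#' @return object of class `bait_set`: tibble with `gene`, `segment`,
#'   `start`, `end`, `seq`.
#' @export
prepare_baits <- function(genes, reference) {
  sq <- as_sequence(reference)
  segs <- list()
  for (g in seq_len(nrow(genes))) {
    runs <- tibble::tibble(start = genes$start[g], end = genes$end[g])
    msk <- genes$masked[[g]]
    for (i in seq_len(nrow(msk))) {
      out <- list()
      for (r in seq_len(nrow(runs))) {
        xs <- runs$start[r]; xe <- runs$end[r]
        ms <- msk$start[i]; me <- msk$end[i]
        if (me < xs || ms > xe) { out[[length(out) + 1]] <- c(xs, xe); next }
        if (ms > xs) out[[length(out) + 1]] <- c(xs, ms - 1L)
        if (me < xe) out[[length(out) + 1]] <- c(me + 1L, xe)
      }
      runs <- if (length(out))
        tibble::tibble(start = as.integer(vapply(out, `[`, 0, 1)),
                       end = as.integer(vapply(out, `[`, 0, 2)))
      else runs[0, ]
    }
    if (nrow(runs) == 0) {
      warning("gene ", genes$name[g], " is fully masked; no bait segments")
      next
    }
    segs[[length(segs) + 1]] <- tibble::tibble(
      gene = genes$name[g],
      segment = paste0(genes$name[g], "_", seq_len(nrow(runs))),
      start = runs$start, end = runs$end,
      seq = substring(sq, runs$start, runs$end))
  }
  structure(dplyr::bind_rows(segs), class = c("bait_set", "tbl_df", "tbl",
                                              "data.frame"))
}

# best chained-anchor score of any bait segment against one read
bait_best_hit <- function(read_seq, baits, k, max_occ = 50) {
  best <- list(gene = NA_character_, score = 0)
  for (i in seq_len(nrow(baits))) {
    for (bs in c(baits$seq[i], revcomp(baits$seq[i]))) {
      ch <- .cpp_chain(bs, read_seq, k, max_occ, 20000L, 2000L)
      if (ch$score > best$score) best <- list(gene = baits$gene[i],
                                              score = ch$score)
    }
  }
  best
}

#' Retain reads with a bait hit
#'
#' A read is kept when a seed-and-chain local match of any bait segment
#' (either orientation) anchors at least `min_hit_score` exact-match bases
#' on it. Retention is per read, independent of the rest of the batch.
#'
#' @param reads tibble with `read_id`, `seq` (or a [simulate_long_reads()]
#'   result, whose `reads` element is used).
#' @param baits a [prepare_baits()] result.
#' @param min_hit_score minimum chained anchor bases. Default 60.
#' @param k seed k-mer length.
#' @param margin when > 0, a read is additionally required to score at least
#'   `margin` anchor bases better on its best gene than on the best other
#'   gene (paralog disambiguation); ties keep the read.
#' @return the retained subset of `reads`, with `bait_hit` and `bait_score`
#'   columns added.
#' @export
bait_filter <- function(reads, baits, min_hit_score = 60, k = 15,
                        margin = 0) {
  if (inherits(reads, "longread_sim")) reads <- reads$reads
  stopifnot(nrow(baits) > 0)
  hits <- purrr::map(reads$seq, function(s) {
    per_gene <- vapply(unique(baits$gene), function(g) {
      bait_best_hit(s, baits[baits$gene == g, ], k)$score
    }, numeric(1))
    o <- order(per_gene, decreasing = TRUE)
    list(gene = unique(baits$gene)[o[1]], score = per_gene[o[1]],
         second = if (length(per_gene) > 1) per_gene[o[2]] else 0)
  })
  score <- vapply(hits, `[[`, 0, "score")
  second <- vapply(hits, `[[`, 0, "second")
  gene <- vapply(hits, `[[`, "", "gene")
  keep <- score >= min_hit_score & (margin <= 0 | score - second >= margin)
  out <- reads[keep, , drop = FALSE]
  out$bait_hit <- gene[keep]
  out$bait_score <- score[keep]
  out
}

#' Trim low-quality read ends
#'
#' Removes `n` bases from both the 5' and 3' ends; reads of length
#' `<= 2 n` become empty and are dropped (a message reports how many).
#'
#' @param reads tibble with `read_id`, `seq`, or a character vector.
#' @param n bases trimmed from each end. Default 23.
#' @return same shape as the input, trimmed, dropped reads removed.
#' @export
trim_ends <- function(reads, n = 23) {
  stopifnot(n >= 0)
  is_chr <- is.character(reads)
  seqs <- if (is_chr) reads else reads$seq
  len <- nchar(seqs)
  keep <- len > 2 * n
  if (any(!keep))
    message(sum(!keep), " read(s) shorter than ", 2 * n + 1,
            " bp dropped by end trimming")
  trimmed <- substr(seqs[keep], n + 1, len[keep] - n)
  if (is_chr) return(trimmed)
  out <- reads[keep, , drop = FALSE]
  out$seq <- trimmed
  out
}

#' Align a long read to a target sequence
#'
#' Exact k-mer seeding, co-linear chaining, then banded affine-gap
#' extension around the chained diagonals, with free end gaps on the
#' target. Tolerant of nanopore-scale error (several percent); structural
#' indels up to the chain's `max_indel` (default 20 kb) are crossed by the
#' chain and absorbed into the band. The reverse complement is tried when
#' the forward orientation yields no chain.
#'
#' @param read_seq single read sequence.
#' @param target target sequence (string or object carrying one).
#' @param k seed k-mer length. Default 15.
#' @param band_pad extra band half-width (bp) beyond the chained diagonal
#'   range. Default 200.
#' @param min_chain_score minimum chained anchor bases to attempt extension.
#' @param match,mismatch,gap_open,gap_ext scoring (gap of length g costs
#'   `gap_open + g * gap_ext`).
#' @param try_rc also try the reverse complement. Default TRUE.
#' @return list with `aligned`; when TRUE also `strand` ("+"/"-"),
#'   `tstart`/`tend` (1-based inclusive target span), `ops`/`lens`
#'   (run-length alignment path over M/X/I/D), `nmatch`, `nmismatch`,
#'   `nins`, `ndel`, `identity` (matches over alignment columns), `score`.
#' @export
align_to_target <- function(read_seq, target, k = 15, band_pad = 200,
                            min_chain_score = 40, match = 2, mismatch = -4,
                            gap_open = 4, gap_ext = 2, try_rc = TRUE) {
  tg <- as_sequence(target)
  unaligned <- list(aligned = FALSE)
  if (nchar(read_seq) < k) return(unaligned)
  strand <- "+"
  ch <- .cpp_chain(read_seq, tg, k, 50L, 20000L, 2000L)
  if (ch$score < min_chain_score && try_rc) {
    rc <- revcomp(read_seq)
    ch_rc <- .cpp_chain(rc, tg, k, 50L, 20000L, 2000L)
    if (ch_rc$score >= min_chain_score) {
      read_seq <- rc; ch <- ch_rc; strand <- "-"
    }
  }
  if (ch$score < min_chain_score) return(unaligned)
  m <- nchar(read_seq)
  wlo <- max(0L, ch$tlo - ch$qlo - band_pad)
  whi <- min(nchar(tg), ch$thi + (m - ch$qhi) + band_pad)
  al <- .cpp_banded_align(read_seq, tg, wlo, whi, ch$dmin, ch$dmax,
                          band_pad, match, mismatch, gap_open, gap_ext)
  if (!isTRUE(al$aligned)) return(unaligned)
  ncols <- al$nmatch + al$nmismatch + al$nins + al$ndel
  list(aligned = TRUE, strand = strand,
       tstart = al$tstart + 1L, tend = al$tend,
       ops = unlist(al$ops), lens = al$lens,
       nmatch = al$nmatch, nmismatch = al$nmismatch,
       nins = al$nins, ndel = al$ndel,
       identity = if (ncols > 0) al$nmatch / ncols else 0,
       score = al$score)
}

# deletion runs of an alignment path in target coordinates, merging runs
# separated by <= merge_within target-consuming (match/mismatch) bases
deletion_clusters <- function(aln, merge_within = 10) {
  tpos <- aln$tstart
  runs <- list()
  for (i in seq_along(aln$ops)) {
    op <- aln$ops[i]; len <- aln$lens[i]
    if (op == "D")
      runs[[length(runs) + 1]] <- c(start = tpos, end = tpos + len - 1)
    if (op %in% c("M", "X", "D")) tpos <- tpos + len
  }
  if (length(runs) == 0)
    return(tibble::tibble(start = integer(), end = integer(),
                          del_bases = integer()))
  runs <- do.call(rbind, runs)
  out <- list()
  cs <- runs[1, "start"]; ce <- runs[1, "end"]; bases <- ce - cs + 1
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs[i, "start"] - ce - 1 # aligned target bases between runs
    if (gap <= merge_within) {
      ce <- runs[i, "end"]
      bases <- bases + runs[i, "end"] - runs[i, "start"] + 1
    } else {
      out[[length(out) + 1]] <- c(cs, ce, bases)
      cs <- runs[i, "start"]; ce <- runs[i, "end"]
      bases <- ce - cs + 1
    }
  }
  out[[length(out) + 1]] <- c(cs, ce, bases)
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                 del_bases = as.integer(m[, 3]))
}

# insertion runs anchored at the preceding target position
insertion_anchors <- function(aln) {
  tpos <- aln$tstart
  out <- list()
  for (i in seq_along(aln$ops)) {
    op <- aln$ops[i]; len <- aln$lens[i]
    if (op == "I")
      out[[length(out) + 1]] <- c(after = tpos - 1, ins_bases = len)
    if (op %in% c("M", "X", "D")) tpos <- tpos + len
  }
  if (length(out) == 0)
    return(tibble::tibble(after = integer(), ins_bases = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(after = as.integer(m[, 1]), ins_bases = as.integer(m[, 2]))
}

#' Classify one read by the diagnostic deletion
#'
#' Aligns the read against the X haplotype around the diagnostic locus. If
#' the alignment spans the locus with at least `flank` anchored target
#' bases on both sides and contains a deletion (gap runs merged across
#' `merge_within` matched bases) of length within `tol` of the expected
#' length overlapping the diagnostic interval, the read is Y-specific;
#' spanning with no such deletion is non-Y; not spanning (or failing to
#' align) is unassigned.
#'
#' @param read_seq read sequence (bait-filtered and trimmed upstream).
#' @param x_seq X haplotype sequence.
#' @param diagnostic list/vector with `start`, `end` (X coordinates) and
#'   optionally `expected_length` (defaults to the interval length).
#' @param flank required anchored bases each side of the locus. Default 200.
#' @param tol tolerated deviation from the expected deletion length (bp).
#'   Default 30.
#' @param merge_within merge gap runs separated by at most this many
#'   aligned bases (noisy reads split long gaps). Default 10.
#' @param ... passed to [align_to_target()].
#' @return one-row tibble: `aligned`, `tstart`, `tend`, `identity`,
#'   `spans_locus`, `deletion_detected`, `observed_length`, `label`
#'   (Y-specific / non-Y / unassigned).
#' @export
classify_read <- function(read_seq, x_seq, diagnostic, flank = 200, tol = 30,
                          merge_within = 10, ...) {
  ds <- diagnostic[["start"]]; de <- diagnostic[["end"]]
  expected <- diagnostic[["expected_length"]] %||% (de - ds + 1)
  aln <- align_to_target(read_seq, x_seq, ...)
  blank <- tibble::tibble(aligned = FALSE, tstart = NA_integer_,
                          tend = NA_integer_, identity = NA_real_,
                          spans_locus = FALSE, deletion_detected = FALSE,
                          observed_length = NA_integer_, label = "unassigned")
  if (!aln$aligned) return(blank)
  spans <- aln$tstart <= ds - flank && aln$tend >= de + flank
  if (!spans)
    return(tibble::tibble(aligned = TRUE, tstart = aln$tstart,
                          tend = aln$tend, identity = aln$identity,
                          spans_locus = FALSE, deletion_detected = FALSE,
                          observed_length = NA_integer_,
                          label = "unassigned"))
  cl <- deletion_clusters(aln, merge_within)
  hit <- cl[cl$start <= de & cl$end >= ds, ]
  observed <- if (nrow(hit)) sum(hit$del_bases) else NA_integer_
  detected <- !is.na(observed) && abs(observed - expected) <= tol
  tibble::tibble(aligned = TRUE, tstart = aln$tstart, tend = aln$tend,
                 identity = aln$identity, spans_locus = TRUE,
                 deletion_detected = detected,
                 observed_length = as.integer(observed),
                 label = if (detected) "Y-specific" else "non-Y")
}

#' Classify a batch of long reads against the X haplotype
#'
#' The full read-labelling workflow: bait filtering on raw reads, end
#' trimming, then per-read diagnostic-deletion classification. Reads are
#' classified independently; reads failing the bait filter are not
#' retained, and retained reads partition exactly into
#' Y-specific / non-Y / unassigned.
#'
#' @param reads tibble with `read_id`, `seq` (or [simulate_long_reads()]
#'   output).
#' @param x_seq X haplotype (string or [generate_reference()] result).
#' @param diagnostic as in [classify_read()]; a [y_variant_spec()] is also
#'   accepted (its diagnostic deletion is used).
#' @param baits optional [prepare_baits()] result; when NULL the bait
#'   filter is skipped.
#' @param trim bases trimmed from each read end after bait filtering.
#'   Default 23.
#' @param min_hit_score,flank,tol passed to the respective stages.
#' @param ... passed to [align_to_target()].
#' @return object of class `read_class`: list with `calls` (one row per
#'   retained read: ReadCall fields), `n_input`, `n_bait_pass`,
#'   `n_trimmed_out`, and the label tally. `tidy()` returns the calls,
#'   `glance()` the tallies.
#' @export
classify_reads <- function(reads, x_seq, diagnostic, baits = NULL,
                           trim = 23, min_hit_score = 60, flank = 200,
                           tol = 30, ...) {
  if (inherits(reads, "longread_sim")) reads <- reads$reads
  if (inherits(diagnostic, "y_variant_spec")) {
    dd <- diagnostic$diagnostic_deletion
    if (is.null(dd)) stop("spec has no diagnostic deletion", call. = FALSE)
    diagnostic <- list(start = dd[1], end = dd[2],
                       expected_length = dd[2] - dd[1] + 1)
  }
  xs <- as_sequence(x_seq)
  n_input <- nrow(reads)
  if (!is.null(baits))
    reads <- bait_filter(reads, baits, min_hit_score = min_hit_score)
  else {
    reads$bait_hit <- NA_character_
    reads$bait_score <- NA_real_
  }
  n_bait <- nrow(reads)
  trimmed <- trim_ends(reads, trim)
  n_trim_out <- n_bait - nrow(trimmed)
  calls <- purrr::map_dfr(seq_len(nrow(trimmed)), function(i) {
    cl <- classify_read(trimmed$seq[i], xs, diagnostic, flank = flank,
                        tol = tol, ...)
    cl$read_id <- trimmed$read_id[i]
    cl$bait_hit <- trimmed$bait_hit[i]
    cl
  })
  if (nrow(calls) == 0)
    calls <- tibble::tibble(aligned = logical(), tstart = integer(),
                            tend = integer(), identity = double(),
                            spans_locus = logical(),
                            deletion_detected = logical(),
                            observed_length = integer(), label = character(),
                            read_id = character(), bait_hit = character())
  calls <- dplyr::relocate(calls, "read_id", "bait_hit")
  structure(list(calls = calls, n_input = n_input, n_bait_pass = n_bait,
                 n_trimmed_out = n_trim_out,
                 labels = table(factor(calls$label,
                                       levels = c("Y-specific", "non-Y",
                                                  "unassigned")))),
            class = "read_class")
}

#' @export
print.read_class <- function(x, ...) {
  cat("<read_class>", x$n_input, "reads in,", x$n_bait_pass,
      "past bait filter;", paste(names(x$labels), as.integer(x$labels),
                                 sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname classify_reads
#' @param x a `read_class` object.
#' @export
tidy.read_class <- function(x, ...) x$calls

#' @rdname classify_reads
#' @export
glance.read_class <- function(x, ...) {
  tibble::tibble(n_input = x$n_input, n_bait_pass = x$n_bait_pass,
                 n_trimmed_out = x$n_trimmed_out,
                 n_y_specific = as.integer(x$labels[["Y-specific"]]),
                 n_non_y = as.integer(x$labels[["non-Y"]]),
                 n_unassigned = as.integer(x$labels[["unassigned"]]))
}

#' Read-span plot over the X haplotype, coloured by label
#'
#' @param object a `read_class` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.read_class <- function(object, ...) {
  d <- object$calls[object$calls$aligned, ]
  d <- d[order(d$tstart), ]
  d$row <- seq_len(nrow(d))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$tstart, xend = .data$tend,
                                       y = .data$row, yend = .data$row,
                                       colour = .data$label),
                          linewidth = 1.2) +
    ggplot2::labs(x = "X-haplotype position (bp)", y = "read",
                  colour = "label") +
    ggplot2::theme_minimal()
}
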