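#' Stack read alignments onto a backbone
#'
#' Star alignment: each read is aligned independently to the backbone
#' (the [align_to_target()] kernel) and its bases, gaps and insertions are
#' recorded per backbone column. Insertions relative to the backbone are
#' kept in per-junction side lists rather than opening new columns.
#'
#' @param reads tibble with `read_id`, `seq`, or a character vector.
#' @param backbone backbone sequence (e.g. the expected Y haplotype).
#' @param ... passed to [align_to_target()].
#' @return object of class `read_stack`: list with `counts` (5 x L matrix:
#'   A/C/G/T/gap per backbone column), `insertions` (tibble: `read_id`,
#'   `after`, `seq`), `depth` (reads covering each column), `backbone_length`,
#'   `n_reads`, `n_unaligned`.
#' @export
stack_alignments <- function(reads, backbone, ...) {
  if (inherits(reads, "longread_sim")) reads <- reads$reads
  if (is.character(reads))
    reads <- tibble::tibble(read_id = sprintf("read_%03d", seq_along(reads)),
                            seq = reads)
  bb <- as_sequence(backbone)
  L <- nchar(bb)
  counts <- matrix(0L, nrow = 5, ncol = L,
                   dimnames = list(c(BASES, "-"), NULL))
  ins <- list()
  n_unaligned <- 0L
  for (i in seq_len(nrow(reads))) {
    aln <- align_to_target(reads$seq[i], bb, ...)
    if (!aln$aligned) {
      warning("read ", reads$read_id[i], " did not align to the backbone; ",
              "excluded")
      n_unaligned <- n_unaligned + 1L
      next
    }
    rseq <- if (aln$strand == "-") revcomp(reads$seq[i]) else reads$seq[i]
    rb <- strsplit(rseq, "", fixed = TRUE)[[1]]
    tpos <- aln$tstart
    qpos <- 1L
    for (r in seq_along(aln$ops)) {
      op <- aln$ops[r]; len <- aln$lens[r]
      if (op %in% c("M", "X")) {
        cols <- tpos:(tpos + len - 1L)
        idx <- match(rb[qpos:(qpos + len - 1L)], BASES)
        ok <- !is.na(idx)
        if (any(ok)) {
          tab <- cbind(idx[ok], cols[ok])
          for (z in seq_len(nrow(tab)))
            counts[tab[z, 1], tab[z, 2]] <- counts[tab[z, 1], tab[z, 2]] + 1L
        }
        tpos <- tpos + len; qpos <- qpos + len
      } else if (op == "D") {
        cols <- tpos:(tpos + len - 1L)
        counts[5, cols] <- counts[5, cols] + 1L
        tpos <- tpos + len
      } else { # I
        ins[[length(ins) + 1]] <- tibble::tibble(
          read_id = reads$read_id[i], after = tpos - 1L,
          seq = paste(rb[qpos:(qpos + len - 1L)], collapse = ""))
        qpos <- qpos + len
      }
    }
  }
  structure(list(counts = counts,
                 insertions = if (length(ins)) dplyr::bind_rows(ins)
                 else tibble::tibble(read_id = character(),
                                     after = integer(), seq = character()),
                 depth = colSums(counts), backbone_length = L,
                 n_reads = nrow(reads) - n_unaligned,
                 n_unaligned = n_unaligned),
            class = "read_stack")
}

#' @export
print.read_stack <- function(x, ...) {
  cov <- sum(x$depth > 0)
  cat("<read_stack>", x$n_reads, "reads on", x$backbone_length,
      "bp backbone;", cov, "columns covered\n")
  invisible(x)
}

#' Call a consensus with IUPAC ambiguity codes from a read stack
#'
#' Per covered column: depth below `min_depth` gives `N`; a gap-majority
#' column is deleted from the consensus; otherwise the majority base is
#' called when its agreement reaches `agreement_threshold`, and the IUPAC
#' code of all bases with at least `iupac_min_frac` support is emitted
#' otherwise. Insertions relative to the backbone are included when at
#' least `insertion_min_frac` of the reads covering the junction carry one,
#' with the plurality sequence. Low read coverage therefore surfaces as
#' runs of ambiguity codes rather than silent errors.
#'
#' @param stack a [stack_alignments()] result.
#' @param min_depth minimum reads per column for a base call. Default 2.
#' @param agreement_threshold majority fraction for an unambiguous call.
#'   Default 0.6.
#' @param iupac_min_frac bases at/above this fraction enter the ambiguity
#'   code. Default 0.25.
#' @param insertion_min_frac covering-read fraction required to emit an
#'   insertion. Default 0.5.
#' @return object of class `consensus_result`: list with `sequence`,
#'   `columns` (tibble: `pos`, `depth`, `agreement`, `call`, `ambiguous`),
#'   `n_ambiguous`, `insertions_applied`, `span` (first/last covered
#'   backbone column). `glance()` summarises.
#' @export
call_consensus <- function(stack, min_depth = 2, agreement_threshold = 0.6,
                           iupac_min_frac = 0.25, insertion_min_frac = 0.5) {
  stopifnot(inherits(stack, "read_stack"))
  depth <- stack$depth
  covered <- which(depth > 0)
  if (length(covered) == 0) {
    warning("no column has coverage; empty consensus")
    return(structure(list(sequence = "",
                          columns = tibble::tibble(pos = integer(),
                                                   depth = integer(),
                                                   agreement = double(),
                                                   call = character(),
                                                   ambiguous = logical()),
                          n_ambiguous = 0L, insertions_applied = 0L,
                          span = c(NA_integer_, NA_integer_)),
                     class = "consensus_result"))
  }
  lo <- min(covered); hi <- max(covered)
  cols <- lo:hi
  cts <- stack$counts[, cols, drop = FALSE]
  d <- depth[cols]
  base_tot <- colSums(cts[1:4, , drop = FALSE])
  gap_frac <- ifelse(d > 0, cts[5, ] / d, 0)

  call <- character(length(cols))
  agreement <- rep(NA_real_, length(cols))
  for (z in seq_along(cols)) {
    if (d[z] < min_depth) { call[z] <- "N"; next }
    if (gap_frac[z] > 0.5) { call[z] <- "-"; next }
    bc <- cts[1:4, z]
    agreement[z] <- max(bc) / base_tot[z]
    if (agreement[z] >= agreement_threshold) {
      call[z] <- BASES[which.max(bc)]
    } else {
      keep <- BASES[bc / base_tot[z] >= iupac_min_frac]
      if (length(keep) == 0) keep <- BASES[which.max(bc)]
      call[z] <- iupac_code(keep)
    }
  }
  ambiguous <- !(call %in% c(BASES, "-"))

  # insertions supported by enough covering reads, plurality sequence
  ins <- stack$insertions
  ins <- ins[ins$after >= lo & ins$after <= hi - 1, , drop = FALSE]
  ins_keep <- tibble::tibble(after = integer(), seq = character())
  if (nrow(ins)) {
    for (a in unique(ins$after)) {
      here <- ins[ins$after == a, ]
      junction_depth <- min(depth[a], depth[a + 1])
      if (junction_depth == 0) next
      if (length(unique(here$read_id)) / junction_depth >=
          insertion_min_frac) {
        top <- names(sort(table(here$seq), decreasing = TRUE))[1]
        ins_keep <- rbind(ins_keep, tibble::tibble(after = a, seq = top))
      }
    }
  }

  pieces <- call[call != "-"]
  pos_kept <- cols[call != "-"]
  for (r in seq_len(nrow(ins_keep))) {
    # splice after the last kept column at/before the anchor
    idx <- findInterval(ins_keep$after[r], pos_kept)
    if (idx == 0) pieces[1] <- paste0(ins_keep$seq[r], pieces[1])
    else pieces[idx] <- paste0(pieces[idx], ins_keep$seq[r])
  }
  sequence <- paste(pieces, collapse = "")

  structure(list(sequence = sequence,
                 columns = tibble::tibble(pos = cols, depth = as.integer(d),
                                          agreement = agreement,
                                          call = call,
                                          ambiguous = ambiguous),
                 n_ambiguous = sum(ambiguous),
                 insertions_applied = nrow(ins_keep),
                 span = c(lo, hi)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>", nchar(x$sequence), "bp,", x$n_ambiguous,
      "ambiguous column(s)\n")
  invisible(x)
}

#' @rdname call_consensus
#' @param x a `consensus_result`.
#' @param ... unused.
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(length = nchar(x$sequence),
                 n_ambiguous = x$n_ambiguous,
                 frac_ambiguous = if (nrow(x$columns))
                   x$n_ambiguous / nrow(x$columns) else NA_real_,
                 mean_depth = if (nrow(x$columns))
                   mean(x$columns$depth) else NA_real_,
                 insertions_applied = x$insertions_applied,
                 span_start = x$span[1], span_end = x$span[2])
}

#' Per-column depth and agreement along the consensus backbone
#'
#' @param object a `consensus_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.consensus_result <- function(object, ...) {
  d <- object$columns
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$depth), width = 1,
                      fill = "grey70") +
    ggplot2::geom_point(data = d[d$ambiguous, ],
                        ggplot2::aes(y = .data$depth), colour = "firebrick",
                        size = 0.6) +
    ggplot2::labs(x = "backbone position (bp)", y = "depth",
                  subtitle = "red: ambiguous columns") +
    ggplot2::theme_minimal()
}
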