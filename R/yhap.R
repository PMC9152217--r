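#' Describe the structural variants that define a Y haplotype
#'
#' A Y variant specification records how the Y differs from the X reference:
#' a tandem duplication (`dup_source` copied and inserted at
#' `dup_insert_at`), deletions / insertions / SNVs carried by the duplicated
#' copy, and the diagnostic deletion that defines Y-origin reads (for the
#' system this package targets, a 275 bp deletion in the truncated copy of
#' the *oaz1* gene).
#'
#' All edit coordinates are 1-based X-reference positions inside
#' `dup_source`; the edits apply to the duplicated copy only, the original
#' region stays intact.
#'
#' @param dup_source length-2 vector `c(start, end)`: X interval that is
#'   tandem-duplicated. `NULL` for an empty spec (Y identical to X).
#' @param dup_insert_at 1-based X position before which the copy is
#'   inserted. Defaults to `dup_source[2] + 1` (a tandem duplication).
#' @param deletions tibble/data.frame with columns `start`, `end` and
#'   optionally `apply` (logical; only consulted for deletions whose size
#'   falls between the keep/apply thresholds of [build_expected_y()]).
#' @param insertions tibble with columns `at` (sequence inserted immediately
#'   after this X position of the copy) and `seq`.
#' @param snvs tibble with columns `pos`, `alt`.
#' @param diagnostic_deletion length-2 vector `c(start, end)`: the
#'   Y-diagnostic deletion inside the copy; always applied.
#' @return object of class `y_variant_spec`.
#' @export
y_variant_spec <- function(dup_source = NULL, dup_insert_at = NULL,
                           deletions = NULL, insertions = NULL,
                           snvs = NULL, diagnostic_deletion = NULL) {
  if (is.null(dup_source)) {
    if (!is.null(deletions) || !is.null(insertions) || !is.null(snvs) ||
        !is.null(diagnostic_deletion))
      stop("edits require a dup_source", call. = FALSE)
    return(structure(list(dup_source = NULL), class = "y_variant_spec"))
  }
  stopifnot(length(dup_source) == 2, dup_source[1] <= dup_source[2])
  if (is.null(dup_insert_at)) dup_insert_at <- dup_source[2] + 1
  stopifnot(dup_insert_at >= 1)

  deletions <- if (is.null(deletions))
    tibble::tibble(start = integer(), end = integer(), apply = logical())
  else tibble::as_tibble(deletions)
  if (!"apply" %in% names(deletions)) deletions$apply <- NA
  insertions <- if (is.null(insertions))
    tibble::tibble(at = integer(), seq = character())
  else tibble::as_tibble(insertions)
  snvs <- if (is.null(snvs)) tibble::tibble(pos = integer(), alt = character())
  else tibble::as_tibble(snvs)

  s <- dup_source[1]; e <- dup_source[2]
  for (i in seq_len(nrow(deletions)))
    check_interval(c(deletions$start[i], deletions$end[i]), s, e, "deletion")
  if (!is.null(diagnostic_deletion))
    check_interval(diagnostic_deletion, s, e, "diagnostic_deletion")
  all_del <- deletions[, c("start", "end")]
  if (!is.null(diagnostic_deletion))
    all_del <- rbind(all_del,
                     tibble::tibble(start = diagnostic_deletion[1],
                                    end = diagnostic_deletion[2]))
  if (nrow(all_del) > 1) {
    o <- order(all_del$start)
    if (any(all_del$start[o][-1] <= all_del$end[o][-nrow(all_del)]))
      stop("deletion intervals overlap (the diagnostic deletion counts as one)",
           call. = FALSE)
  }
  if (nrow(insertions) && any(insertions$at < s | insertions$at > e))
    stop("insertion position outside dup_source", call. = FALSE)
  if (nrow(snvs)) {
    if (any(snvs$pos < s | snvs$pos > e))
      stop("SNV position outside dup_source", call. = FALSE)
    if (!all(snvs$alt %in% BASES)) stop("SNV alt must be A/C/G/T", call. = FALSE)
  }

  structure(list(dup_source = as.integer(dup_source),
                 dup_insert_at = as.integer(dup_insert_at),
                 deletions = deletions, insertions = insertions, snvs = snvs,
                 diagnostic_deletion =
                   if (is.null(diagnostic_deletion)) NULL
                   else as.integer(diagnostic_deletion)),
            class = "y_variant_spec")
}

#' @export
print.y_variant_spec <- function(x, ...) {
  if (is.null(x$dup_source)) {
    cat("<y_variant_spec> empty (Y identical to X)\n")
    return(invisible(x))
  }
  cat("<y_variant_spec>\n")
  cat("  duplication: [", x$dup_source[1], ", ", x$dup_source[2], "] (",
      x$dup_source[2] - x$dup_source[1] + 1, " bp) inserted at ",
      x$dup_insert_at, "\n", sep = "")
  cat("  deletions: ", nrow(x$deletions), " | insertions: ",
      nrow(x$insertions), " | SNVs: ", nrow(x$snvs), "\n", sep = "")
  if (!is.null(x$diagnostic_deletion))
    cat("  diagnostic deletion: [", x$diagnostic_deletion[1], ", ",
        x$diagnostic_deletion[2], "] (",
        x$diagnostic_deletion[2] - x$diagnostic_deletion[1] + 1, " bp)\n",
        sep = "")
  invisible(x)
}

# Core builder shared by make_true_y() and build_expected_y().
# apply_flags: logical per row of spec$deletions (diagnostic always applied).
build_y_core <- function(x_seq, spec, apply_flags) {
  L <- nchar(x_seq)
  if (is.null(spec$dup_source)) {
    return(list(
      y_seq = x_seq,
      coord_map = tibble::tibble(y_start = 1L, y_end = L, x_start = 1L,
                                 x_end = L, tag = "original"),
      deletions = tibble::tibble(start = integer(), end = integer(),
                                 length = integer(), applied = logical(),
                                 diagnostic = logical())))
  }
  s <- spec$dup_source[1]; e <- spec$dup_source[2]
  if (e > L) stop("dup_source outside reference", call. = FALSE)
  ins_at <- spec$dup_insert_at
  if (ins_at > L + 1) stop("dup_insert_at outside reference", call. = FALSE)

  dels <- spec$deletions
  dels$length <- dels$end - dels$start + 1L
  dels$applied <- apply_flags
  dels$diagnostic <- FALSE
  if (!is.null(spec$diagnostic_deletion)) {
    dd <- spec$diagnostic_deletion
    dels <- rbind(dels[, c("start", "end", "length", "applied", "diagnostic")],
                  tibble::tibble(start = dd[1], end = dd[2],
                                 length = dd[2] - dd[1] + 1L,
                                 applied = TRUE, diagnostic = TRUE))
  } else {
    dels <- dels[, c("start", "end", "length", "applied", "diagnostic")]
  }
  dels <- dels[order(dels$start), ]

  # kept X intervals of the copy = [s, e] minus applied deletions
  kept <- tibble::tibble(xs = s, xe = e)
  for (i in which(dels$applied)) {
    ds <- dels$start[i]; de <- dels$end[i]
    out <- list()
    for (r in seq_len(nrow(kept))) {
      xs <- kept$xs[r]; xe <- kept$xe[r]
      if (de < xs || ds > xe) { out[[length(out) + 1]] <- c(xs, xe); next }
      if (ds > xs) out[[length(out) + 1]] <- c(xs, ds - 1L)
      if (de < xe) out[[length(out) + 1]] <- c(de + 1L, xe)
    }
    kept <- tibble::tibble(xs = as.integer(vapply(out, `[`, 0, 1)),
                           xe = as.integer(vapply(out, `[`, 0, 2)))
  }

  # pieces: x-derived intervals interleaved with literal insertions
  pieces <- lapply(seq_len(nrow(kept)), function(r)
    list(type = "x", xs = kept$xs[r], xe = kept$xe[r]))
  ins <- spec$insertions
  if (nrow(ins)) {
    for (i in order(ins$at, decreasing = TRUE)) {
      at <- ins$at[i]; sq <- ins$seq[i]
      hit <- NULL
      for (p in seq_along(pieces)) {
        pc <- pieces[[p]]
        if (pc$type == "x" && at >= pc$xs && at <= pc$xe) { hit <- p; break }
      }
      if (is.null(hit)) {
        warning("insertion at ", at, " falls inside an applied deletion; skipped")
        next
      }
      pc <- pieces[[hit]]
      repl <- list()
      repl[[1]] <- list(type = "x", xs = pc$xs, xe = at)
      repl[[2]] <- list(type = "lit", seq = sq)
      if (at < pc$xe) repl[[3]] <- list(type = "x", xs = at + 1L, xe = pc$xe)
      pieces <- append(pieces[-hit], repl, after = hit - 1L)
    }
  }

  # copy sequence with SNVs applied
  snvs <- spec$snvs
  piece_seq <- vapply(pieces, function(pc) {
    if (pc$type == "lit") return(pc$seq)
    sq <- substr(x_seq, pc$xs, pc$xe)
    if (nrow(snvs)) {
      hit <- which(snvs$pos >= pc$xs & snvs$pos <= pc$xe)
      for (i in hit) substr(sq, snvs$pos[i] - pc$xs + 1L,
                            snvs$pos[i] - pc$xs + 1L) <- snvs$alt[i]
    }
    sq
  }, character(1))

  prefix <- if (ins_at > 1) substr(x_seq, 1, ins_at - 1) else ""
  suffix <- if (ins_at <= L) substr(x_seq, ins_at, L) else ""
  y_seq <- paste0(prefix, paste(piece_seq, collapse = ""), suffix)

  # coordinate map (run-length segments)
  seg <- list()
  ypos <- 0L
  if (nchar(prefix) > 0) {
    seg[[1]] <- tibble::tibble(y_start = 1L, y_end = nchar(prefix),
                               x_start = 1L, x_end = ins_at - 1L,
                               tag = "original")
    ypos <- nchar(prefix)
  }
  for (p in seq_along(pieces)) {
    pc <- pieces[[p]]
    n <- nchar(piece_seq[p])
    if (n == 0) next
    seg[[length(seg) + 1]] <- if (pc$type == "x")
      tibble::tibble(y_start = ypos + 1L, y_end = ypos + n,
                     x_start = pc$xs, x_end = pc$xe, tag = "duplicate")
    else
      tibble::tibble(y_start = ypos + 1L, y_end = ypos + n,
                     x_start = NA_integer_, x_end = NA_integer_,
                     tag = "insertion")
    ypos <- ypos + n
  }
  if (nchar(suffix) > 0) {
    seg[[length(seg) + 1]] <-
      tibble::tibble(y_start = ypos + 1L, y_end = ypos + nchar(suffix),
                     x_start = ins_at, x_end = L, tag = "original")
  }
  list(y_seq = y_seq, coord_map = dplyr::bind_rows(seg), deletions = dels)
}

#' Build the expected Y haplotype from the X reference and a variant spec
#'
#' Applies the reconstruction rule used for reference-guided expected-Y
#' haplotypes: the duplicated copy is inserted at its breakpoint; deletions
#' shorter than `small_del_keep_below` are *not* applied (long reads cross
#' them, so keeping the sequence preserves mappability); deletions of at
#' least `large_del_apply_at_or_above` *are* applied; the diagnostic
#' deletion is always applied, since it is what defines the Y. Deletions
#' whose size falls between the two thresholds are refused unless the
#' spec's deletions table carries an explicit `apply` value for them.
#'
#' @param x reference X haplotype: a string or [generate_reference()] output.
#' @param genes optional gene-model tibble (see [gene_model()]); carried for
#'   annotation liftover.
#' @param spec a [y_variant_spec()].
#' @param small_del_keep_below deletions shorter than this many bp are kept
#'   (sequence retained) in the expected Y. Default 500.
#' @param large_del_apply_at_or_above deletions at least this many bp are
#'   removed. Default 5000.
#' @return object of class `haplotype_model` with elements `x_seq`, `genes`,
#'   `spec`, `y_seq`, `coord_map` (tibble: `y_start`, `y_end`, `x_start`,
#'   `x_end`, `tag` in original/duplicate/insertion) and `deletions`
#'   (with an `applied` flag per deletion).
#' @export
build_expected_y <- function(x, genes = NULL, spec = y_variant_spec(),
                             small_del_keep_below = 500,
                             large_del_apply_at_or_above = 5000) {
  if (inherits(x, "ref_haplotype") && is.null(genes)) genes <- x$genes
  chrom <- if (inherits(x, "ref_haplotype")) x$chrom else "chr"
  x_seq <- as_sequence(x)
  stopifnot(inherits(spec, "y_variant_spec"),
            small_del_keep_below <= large_del_apply_at_or_above)

  dels <- spec$deletions %||%
    tibble::tibble(start = integer(), end = integer(), apply = logical())
  flags <- logical(nrow(dels))
  if (nrow(dels)) {
    len <- dels$end - dels$start + 1
    for (i in seq_len(nrow(dels))) {
      if (len[i] < small_del_keep_below) flags[i] <- FALSE
      else if (len[i] >= large_del_apply_at_or_above) flags[i] <- TRUE
      else if (!is.na(dels$apply[i])) flags[i] <- dels$apply[i]
      else stop("deletion [", dels$start[i], ", ", dels$end[i], "] is ",
                len[i], " bp, between small_del_keep_below (",
                small_del_keep_below, ") and large_del_apply_at_or_above (",
                large_del_apply_at_or_above, "); no rule covers this size ",
                "class - set an explicit `apply` value for it in the spec",
                call. = FALSE)
    }
  }
  core <- build_y_core(x_seq, spec, flags)
  structure(list(chrom = chrom, x_seq = x_seq, genes = genes, spec = spec,
                 y_seq = core$y_seq, coord_map = core$coord_map,
                 deletions = core$deletions,
                 thresholds = c(small = small_del_keep_below,
                                large = large_del_apply_at_or_above)),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat("<haplotype_model> X:", nchar(x$x_seq), "bp -> expected Y:",
      nchar(x$y_seq), "bp\n")
  if (!is.null(x$spec$dup_source))
    cat("  duplication [", x$spec$dup_source[1], ", ", x$spec$dup_source[2],
        "]; deletions applied: ", sum(x$deletions$applied), "/",
        nrow(x$deletions), "\n", sep = "")
  invisible(x)
}

#' Lift X annotations onto the constructed Y haplotype
#'
#' Features on the original region are shifted past the inserted copy;
#' every X feature overlapping the duplication source appears a second time
#' on the duplicated copy (suffixed `_dup`). Copy features truncated by an
#' applied deletion are flagged, and two copy features fused by a deletion
#' that removes the entire interval between them are emitted as a single
#' chimeric feature named `geneA-geneB_chimera` (upstream gene first).
#'
#' @param model a [build_expected_y()] result.
#' @return tibble with columns `chrom`, `start`, `end`, `strand`, `name`,
#'   `copy` ("original"/"duplicate") and `flag`
#'   ("ok"/"truncated"/"chimera"/"contains_insertion").
#' @export
liftover_annotations <- function(model) {
  stopifnot(inherits(model, "haplotype_model"))
  genes <- model$genes
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          name = character(), copy = character(),
                          flag = character())
  if (is.null(genes) || nrow(genes) == 0) return(empty)
  spec <- model$spec
  if (is.null(spec$dup_source)) {
    return(tibble::tibble(chrom = model$chrom, start = genes$start,
                          end = genes$end, strand = genes$strand,
                          name = genes$name, copy = "original", flag = "ok"))
  }
  copy_len <- nchar(model$y_seq) - nchar(model$x_seq)
  ins_at <- spec$dup_insert_at

  orig <- tibble::tibble(
    chrom = model$chrom,
    start = ifelse(genes$start >= ins_at, genes$start + copy_len, genes$start),
    end = ifelse(genes$end >= ins_at, genes$end + copy_len, genes$end),
    strand = genes$strand, name = genes$name, copy = "original",
    flag = ifelse(genes$start < ins_at & genes$end >= ins_at,
                  "contains_insertion", "ok"))

  # duplicate-copy features, projected through the coord map
  dupseg <- model$coord_map[model$coord_map$tag == "duplicate", ]
  s <- spec$dup_source[1]; e <- spec$dup_source[2]
  proj <- list()
  for (g in seq_len(nrow(genes))) {
    gs <- max(genes$start[g], s); ge <- min(genes$end[g], e)
    if (gs > ge) next
    hit <- dupseg[dupseg$x_start <= ge & dupseg$x_end >= gs, ]
    if (nrow(hit) == 0) next # gene fully removed from the copy
    ys <- hit$y_start + pmax(gs - hit$x_start, 0)
    ye <- hit$y_end - pmax(hit$x_end - ge, 0)
    retained <- sum(ye - ys + 1)
    proj[[length(proj) + 1]] <- tibble::tibble(
      name = genes$name[g], strand = genes$strand[g],
      xs = gs, xe = ge, y_start = min(ys), y_end = max(ye),
      truncated = retained < (ge - gs + 1))
  }
  dup <- dplyr::bind_rows(proj)

  # chimera: an applied deletion removing the entire gap between two
  # truncated copy genes fuses them into one feature
  fused <- rep(FALSE, nrow(dup))
  chim <- list()
  applied <- model$deletions[model$deletions$applied, ]
  if (nrow(dup) > 1 && nrow(applied)) {
    for (d in seq_len(nrow(applied))) {
      ds <- applied$start[d]; de <- applied$end[d]
      for (a in seq_len(nrow(dup) - 1)) {
        b <- a + 1
        if (fused[a] || fused[b]) next
        gapless <- ds <= dup$xe[a] && de >= dup$xs[b] && dup$xe[a] < dup$xs[b]
        if (gapless) {
          chim[[length(chim) + 1]] <- tibble::tibble(
            chrom = model$chrom, start = dup$y_start[a], end = dup$y_end[b],
            strand = dup$strand[a],
            name = paste0(dup$name[a], "-", dup$name[b], "_chimera"),
            copy = "duplicate", flag = "chimera")
          fused[c(a, b)] <- TRUE
        }
      }
    }
  }
  dup_rows <- if (nrow(dup)) tibble::tibble(
    chrom = model$chrom, start = dup$y_start, end = dup$y_end,
    strand = dup$strand, name = paste0(dup$name, "_dup"), copy = "duplicate",
    flag = ifelse(dup$truncated, "truncated", "ok"))[!fused, ] else empty

  out <- dplyr::bind_rows(orig, dup_rows, dplyr::bind_rows(chim))
  dplyr::arrange(out, .data$start, .data$end)
}

#' Extract a 1-based inclusive region from a sequence
#'
#' @param x sequence (string or an object carrying one).
#' @param start,end 1-based inclusive coordinates.
#' @return the subsequence, of length `end - start + 1`.
#' @export
extract_region <- function(x, start, end) {
  sq <- as_sequence(x)
  stopifnot(length(start) == 1, length(end) == 1)
  if (start < 1 || end > nchar(sq) || start > end)
    stop("region [", start, ", ", end, "] out of bounds for sequence of ",
         nchar(sq), " bp", call. = FALSE)
  substr(sq, start, end)
}

#' Map Y positions back to their X origin
#'
#' @param model a [build_expected_y()] or [make_true_y()] result.
#' @param y_pos vector of 1-based Y positions.
#' @return tibble with `y_pos`, `x_pos` (NA for bases with no X origin) and
#'   `tag` ("original", "duplicate" or "insertion").
#' @export
y_to_x <- function(model, y_pos) {
  cm <- model$coord_map
  if (any(y_pos < 1 | y_pos > max(cm$y_end)))
    stop("y_pos out of range [1, ", max(cm$y_end), "]", call. = FALSE)
  idx <- findInterval(y_pos, cm$y_start)
  tag <- cm$tag[idx]
  x_pos <- ifelse(tag == "insertion", NA_integer_,
                  cm$x_start[idx] + (y_pos - cm$y_start[idx]))
  tibble::tibble(y_pos = as.integer(y_pos), x_pos = as.integer(x_pos),
                 tag = tag)
}
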