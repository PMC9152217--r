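# file formats: Popoolation2 sync, FASTA/FASTQ, BED, YAML pipeline config

SYNC_ORDER <- c("A", "T", "C", "G", "N", "del") # sync column dialect

#' Read a Popoolation2 sync file
#'
#' Tab-separated, one line per site: `chrom pos refbase` then one
#' colon-separated `A:T:C:G:N:del` count column per pool (two pools
#' expected). Malformed lines are skipped, counted and reported.
#'
#' @param path file path.
#' @param pool_order which file column is pool1/pool2; `c(2, 1)` swaps
#'   them (by convention pool1 = females, pool2 = males).
#' @return pooled-counts tibble (`chrom`, `pos`, `ref`, `pool1_*`,
#'   `pool2_*`), with attribute `n_rejected`.
#' @export
read_sync <- function(path, pool_order = c(1, 2)) {
  stopifnot(length(pool_order) == 2, setequal(pool_order, 1:2))
  lines <- readr::read_lines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  empty <- tibble::as_tibble(c(
    list(chrom = character(), pos = integer(), ref = character()),
    setNames(rep(list(integer()), 12),
             paste0(rep(c("pool1_", "pool2_"), each = 6), SYNC_ORDER))))
  if (length(lines) == 0) {
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  parse_pool <- function(col) {
    parts <- strsplit(col, ":", fixed = TRUE)
    ok <- lengths(parts) == 6
    m <- matrix(NA_integer_, length(col), 6)
    if (any(ok))
      m[ok, ] <- matrix(suppressWarnings(
        as.integer(unlist(parts[ok]))), ncol = 6, byrow = TRUE)
    m
  }
  ok <- nf == 5
  f <- fields[ok]
  chrom <- vapply(f, `[`, "", 1)
  pos <- suppressWarnings(as.integer(vapply(f, `[`, "", 2)))
  ref <- vapply(f, `[`, "", 3)
  p1 <- parse_pool(vapply(f, `[`, "", 3 + pool_order[1]))
  p2 <- parse_pool(vapply(f, `[`, "", 3 + pool_order[2]))
  good <- !is.na(pos) & !apply(is.na(p1), 1, any) & !apply(is.na(p2), 1, any)
  n_rejected <- sum(!ok) + sum(!good)
  if (n_rejected > 0)
    message(n_rejected, " malformed sync line(s) skipped")
  out <- tibble::tibble(chrom = chrom[good], pos = pos[good],
                        ref = ref[good])
  # emit in A/C/G/T/N/del order regardless of the sync column dialect
  for (b in c("A", "C", "G", "T", "N", "del"))
    out[[paste0("pool1_", b)]] <- p1[good, match(b, SYNC_ORDER)]
  for (b in c("A", "C", "G", "T", "N", "del"))
    out[[paste0("pool2_", b)]] <- p2[good, match(b, SYNC_ORDER)]
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write pooled counts as a Popoolation2 sync file
#'
#' @param counts pooled-counts tibble (see [read_sync()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(counts, path) {
  pool_col <- function(prefix) {
    cols <- paste0(prefix, "_", SYNC_ORDER)
    m <- as.matrix(counts[, cols])
    apply(m, 1, paste, collapse = ":")
  }
  if (nrow(counts) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  lines <- paste(counts$chrom, counts$pos, counts$ref,
                 pool_col("pool1"), pool_col("pool2"), sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path file path.
#' @return tibble with `id` (first word of the header) and `seq`; sequence
#'   case is preserved. CRLF line endings are handled.
#' @export
read_fasta <- function(path) {
  lines <- sub("\r$", "", readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(tibble::tibble(id = character(), seq = character()))
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  # records with no sequence lines come back empty
  seqs <- seqs[match(seq_along(ids), as.integer(names(seqs)))]
  seqs[is.na(seqs)] <- ""
  tibble::tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x tibble with `id`, `seq`, or a named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x))
    x <- tibble::tibble(id = names(x) %||% sprintf("seq_%d", seq_along(x)),
                        seq = unname(x))
  out <- character(0)
  for (i in seq_len(nrow(x))) {
    s <- x$seq[i]
    body <- if (nchar(s) == 0) character(0)
    else substring(s, seq(1, nchar(s), width),
                   pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    out <- c(out, paste0(">", x$id[i]), body)
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path file path.
#' @return tibble with `id`, `seq`, `qual` (qualities carried but unused
#'   downstream).
#' @export
read_fastq <- function(path) {
  lines <- sub("\r$", "", readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(tibble::tibble(id = character(), seq = character(),
                          qual = character()))
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ: ", path, call. = FALSE)
  i <- seq(1, length(lines), by = 4)
  ids <- sub("^@", "", lines[i])
  ids <- sub("\\s.*$", "", ids)
  tibble::tibble(id = ids, seq = lines[i + 1], qual = lines[i + 3])
}

#' Write reads to FASTQ with a constant quality derived from an error rate
#'
#' @param reads tibble with `read_id` (or `id`) and `seq`.
#' @param path output path.
#' @param error_rate per-base error rate mapped to a constant Phred
#'   quality character.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, error_rate = 0.0644) {
  id <- if ("read_id" %in% names(reads)) reads$read_id else reads$id
  q <- max(2L, min(40L, as.integer(round(-10 * log10(max(error_rate,
                                                         1e-4))))))
  qc <- rawToChar(as.raw(q + 33L))
  lines <- as.vector(rbind(paste0("@", id), reads$seq, "+",
                           vapply(nchar(reads$seq),
                                  function(n) strrep(qc, n), "")))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write an annotation tibble as BED (0-based half-open)
#'
#' @param ann tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `name`, optionally `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  strand <- if ("strand" %in% names(ann)) ann$strand else rep(".", nrow(ann))
  lines <- paste(ann$chrom, ann$start - 1L, ann$end, ann$name, 0, strand,
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

# --- pipeline configuration ---------------------------------------------

config_known_keys <- list(
  top = c("preset", "seed", "region_length", "gc", "scale", "pool",
          "scan", "long_reads", "n_reads_x", "n_reads_y", "classify",
          "consensus"),
  pool = c("n_per_sex", "depth_mean", "seq_error", "snp_density",
           "sexlinked_snp_density", "sex_system", "subsample_fraction",
           "seed"),
  scan = c("fixed_threshold", "min_polymorphic_freq", "max_polymorphic_freq",
           "min_depth", "max_depth", "min_read_count", "window_size"),
  long_reads = c("error_rate", "mix", "length_meanlog", "length_sdlog",
                 "length_min", "seed"),
  classify = c("trim", "min_hit_score", "flank", "tol"),
  consensus = c("min_depth", "agreement_threshold", "iupac_min_frac",
                "insertion_min_frac"))

#' Read and validate a pipeline configuration file
#'
#' YAML round-trips losslessly through [write_pipeline_config()]; unknown
#' keys are rejected so typos fail loudly rather than being ignored.
#'
#' @param path YAML file.
#' @return named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg configuration list.
#' @export
validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_known_keys$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in intersect(names(cfg),
                        setdiff(names(config_known_keys), "top"))) {
    bad <- setdiff(names(cfg[[sec]]), config_known_keys[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$seed))
    stop("config must set an explicit seed (no wall-clock default)",
         call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
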