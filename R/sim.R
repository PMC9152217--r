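#' Define a gene model on the reference
#'
#' @param name gene label.
#' @param start,end 1-based inclusive gene span.
#' @param strand "+" or "-".
#' @param exons optional tibble/data.frame with `start`, `end` (1-based,
#'   inclusive, within the span, sorted, non-overlapping). Defaults to one
#'   exon covering the whole span.
#' @param masked optional tibble with `start`, `end`: intervals excluded
#'   from bait construction (e.g. an intron resembling an unrelated gene).
#' @return one-row tibble with list-columns `exons` and `masked`; rows for
#'   several genes combine with [dplyr::bind_rows()].
#' @export
gene_model <- function(name, start, end, strand = "+", exons = NULL,
                       masked = NULL) {
  stopifnot(start >= 1, start <= end, strand %in% c("+", "-"))
  if (is.null(exons)) exons <- tibble::tibble(start = start, end = end)
  exons <- tibble::as_tibble(exons)
  if (any(exons$start < start | exons$end > end | exons$start > exons$end))
    stop("exons must lie within the gene span", call. = FALSE)
  if (is.unsorted(exons$start) ||
      (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])))
    stop("exons must be sorted and non-overlapping", call. = FALSE)
  masked <- if (is.null(masked)) tibble::tibble(start = integer(),
                                                end = integer())
  else tibble::as_tibble(masked)
  if (nrow(masked) && any(masked$start < start | masked$end > end))
    stop("masked intervals must lie within the gene span", call. = FALSE)
  tibble::tibble(name = name, start = as.integer(start), end = as.integer(end),
                 strand = strand, exons = list(exons), masked = list(masked))
}

#' Generate a random reference haplotype with gene annotations
#'
#' @param length reference length in bp.
#' @param genes optional gene-model tibble ([gene_model()] rows); genes must
#'   not overlap each other and must fit inside the reference.
#' @param gc GC fraction of the simulated sequence. Default 0.41.
#' @param seed integer seed; identical calls give byte-identical output.
#' @param chrom chromosome label used in emitted tables.
#' @return object of class `ref_haplotype`: list with `chrom`, `seq` and the
#'   `genes` tibble.
#' @export
generate_reference <- function(length, genes = NULL, gc = 0.41, seed = NULL,
                               chrom = "chrSim") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  if (!is.null(genes) && nrow(genes)) {
    if (any(genes$start < 1 | genes$end > length))
      stop("gene outside reference", call. = FALSE)
    o <- order(genes$start)
    if (nrow(genes) > 1 &&
        any(genes$start[o][-1] <= genes$end[o][-nrow(genes)]))
      stop("overlapping genes: gene spans must be disjoint", call. = FALSE)
  }
  seq <- local_seed(seed, random_dna(length, gc))
  structure(list(chrom = chrom, seq = seq,
                 genes = if (is.null(genes))
                   gene_model("none", 1, 1)[0, ] else genes),
            class = "ref_haplotype")
}

#' @export
print.ref_haplotype <- function(x, ...) {
  cat("<ref_haplotype>", x$chrom, "-", nchar(x$seq), "bp,",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Annotation table for a reference haplotype
#'
#' @param ref a [generate_reference()] result.
#' @return tibble with `chrom`, `start`, `end`, `strand`, `name`, `type`
#'   ("gene" or "exon"), 1-based inclusive coordinates.
#' @export
annotation_table <- function(ref) {
  stopifnot(inherits(ref, "ref_haplotype"))
  genes <- ref$genes
  if (nrow(genes) == 0)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          name = character(), type = character()))
  g <- tibble::tibble(chrom = ref$chrom, start = genes$start, end = genes$end,
                      strand = genes$strand, name = genes$name, type = "gene")
  ex <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    e <- genes$exons[[i]]
    if (nrow(e) == 0) return(NULL)
    tibble::tibble(chrom = ref$chrom, start = e$start, end = e$end,
                   strand = genes$strand[i],
                   name = paste0(genes$name[i], ".exon", seq_len(nrow(e))),
                   type = "exon")
  })
  dplyr::arrange(dplyr::bind_rows(g, ex), .data$start, .data$end)
}

#' Construct the true Y haplotype for simulation
#'
#' Unlike [build_expected_y()], which follows the reconstruction rule of
#' keeping small deletions, the true Y applies *every* edit in the spec:
#' this is the haplotype the simulated Y-origin long reads are drawn from.
#'
#' @param reference X haplotype (string or [generate_reference()] result).
#' @param spec a [y_variant_spec()].
#' @return object of class `y_haplotype`: list with `y_seq`, `coord_map`
#'   (the truth map relating every Y base to its X origin) and `deletions`.
#' @export
make_true_y <- function(reference, spec) {
  x_seq <- as_sequence(reference)
  stopifnot(inherits(spec, "y_variant_spec"))
  core <- build_y_core(x_seq, spec, rep(TRUE, nrow(spec$deletions %||% tibble::tibble())))
  structure(list(y_seq = core$y_seq, coord_map = core$coord_map,
                 deletions = core$deletions, spec = spec),
            class = "y_haplotype")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.y_haplotype <- function(x, ...) {
  cat("<y_haplotype>", nchar(x$y_seq), "bp (true Y)\n")
  invisible(x)
}

#' Configuration for pooled-count simulation
#'
#' Defaults mirror a pooled whole-genome resequencing design: pools of 10
#' individuals per sex at a mean pooled depth of 170x (10 samples at ~17x),
#' thinned to a 20% read subsample, giving ~34x realised depth per pool.
#'
#' @param n_per_sex individuals per pool.
#' @param depth_mean expected pooled reads per site per pool (before
#'   subsampling).
#' @param seq_error per-base sequencing error probability.
#' @param snp_density background polymorphic sites per kb.
#' @param sexlinked_snp_density fully sex-linked sites per kb inside the sex
#'   region (XY systems only).
#' @param sex_system "XY" or "none".
#' @param subsample_fraction fraction of reads retained per pool.
#' @param seed integer seed.
#' @return object of class `pool_sim_config`.
#' @export
pool_sim_config <- function(n_per_sex = 10, depth_mean = 170,
                            seq_error = 0.002, snp_density = 1,
                            sexlinked_snp_density = 5,
                            sex_system = c("XY", "none"),
                            subsample_fraction = 0.2, seed = NULL) {
  sex_system <- match.arg(sex_system)
  stopifnot(n_per_sex >= 1, depth_mean > 0,
            seq_error >= 0, seq_error <= 1,
            subsample_fraction > 0, subsample_fraction <= 1,
            snp_density >= 0, sexlinked_snp_density >= 0)
  structure(list(n_per_sex = n_per_sex, depth_mean = depth_mean,
                 seq_error = seq_error, snp_density = snp_density,
                 sexlinked_snp_density = sexlinked_snp_density,
                 sex_system = sex_system,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "pool_sim_config")
}

# move sequencing errors between base columns of a site x 4 count matrix
perturb_counts <- function(m, seq_error) {
  if (seq_error <= 0) return(m)
  out <- m
  for (b in 1:4) {
    err <- rbinom(nrow(m), m[, b], seq_error)
    out[, b] <- out[, b] - err
    x1 <- rbinom(nrow(m), err, 1 / 3)
    x2 <- rbinom(nrow(m), err - x1, 1 / 2)
    x3 <- err - x1 - x2
    to <- setdiff(1:4, b)
    out[, to[1]] <- out[, to[1]] + x1
    out[, to[2]] <- out[, to[2]] + x2
    out[, to[3]] <- out[, to[3]] + x3
  }
  out
}

#' Simulate pooled allele counts for a male and a female pool
#'
#' At each background polymorphic site, both sexes share a population allele
#' frequency; each pool's 2*`n_per_sex` chromosomes are a binomial draw from
#' it. At sex-linked sites (XY system, inside `sex_region`) the female pool
#' carries only X alleles while the male pool is X/Y heterozygous, so the
#' Y allele sits at frequency 0 in females and exactly 0.5 among male
#' chromosomes. Read depth is Poisson per site per pool, thinned
#' independently by `subsample_fraction`; reads sample pool chromosomes
#' binomially and each sampled base is flipped to a uniformly chosen other
#' base with probability `seq_error`. Only polymorphic sites are emitted.
#'
#' @param reference X haplotype ([generate_reference()] result or string).
#' @param cfg a [pool_sim_config()].
#' @param sex_region length-2 vector: X interval harbouring the sex-linked
#'   sites (required when `cfg$sex_system == "XY"`); typically the
#'   duplication source interval of the Y spec.
#' @return list of class `pool_sim` with `counts` (tibble: `chrom`, `pos`,
#'   `ref`, `pool1_*` female counts, `pool2_*` male counts over
#'   A/C/G/T/N/del) and `truth` (tibble: `pos`, `sex_linked`, `ref`, `alt`,
#'   chromosome-level allele frequencies per pool).
#' @export
simulate_pool_counts <- function(reference, cfg = pool_sim_config(),
                                 sex_region = NULL) {
  stopifnot(inherits(cfg, "pool_sim_config"))
  x_seq <- as_sequence(reference)
  chrom <- if (inherits(reference, "ref_haplotype")) reference$chrom else "chr"
  L <- nchar(x_seq)
  if (cfg$sex_system == "XY" && is.null(sex_region))
    stop("sex_system = 'XY' requires a sex_region interval", call. = FALSE)

  local_seed(cfg$seed, {
    n_bg <- round(L / 1000 * cfg$snp_density)
    bg_pos <- sort(sample.int(L, min(n_bg, L)))
    sl_pos <- integer()
    if (cfg$sex_system == "XY") {
      check_interval(sex_region, 1, L, "sex_region")
      span <- sex_region[2] - sex_region[1] + 1
      n_sl <- round(span / 1000 * cfg$sexlinked_snp_density)
      sl_pos <- sort(sex_region[1] - 1L +
                       sample.int(span, min(n_sl, span)))
      bg_pos <- setdiff(bg_pos, sl_pos)
    }
    pos <- sort(c(bg_pos, sl_pos))
    sexlinked <- pos %in% sl_pos
    n <- length(pos)
    if (n == 0)
      return(structure(list(counts = tibble::tibble(), truth = tibble::tibble()),
                       class = "pool_sim"))

    ref <- strsplit(x_seq, "", fixed = TRUE)[[1]][pos]
    alt <- other_base(ref)
    chr2n <- 2L * cfg$n_per_sex

    # chromosome-level alt frequency per pool
    p_pop <- runif(n, 0.1, 0.9)
    f1 <- ifelse(sexlinked, 0, rbinom(n, chr2n, p_pop) / chr2n)  # females
    f2 <- ifelse(sexlinked, 0.5, rbinom(n, chr2n, p_pop) / chr2n) # males

    depth1 <- rbinom(n, rpois(n, cfg$depth_mean), cfg$subsample_fraction)
    depth2 <- rbinom(n, rpois(n, cfg$depth_mean), cfg$subsample_fraction)

    base_idx <- function(b) match(b, BASES)
    mk <- function(depth, f) {
      altn <- rbinom(n, depth, f)
      m <- matrix(0L, n, 4)
      m[cbind(seq_len(n), base_idx(ref))] <- depth - altn
      m[cbind(seq_len(n), base_idx(alt))] <-
        m[cbind(seq_len(n), base_idx(alt))] + altn
      perturb_counts(m, cfg$seq_error)
    }
    m1 <- mk(depth1, f1)
    m2 <- mk(depth2, f2)

    counts <- tibble::tibble(
      chrom = chrom, pos = as.integer(pos), ref = ref,
      pool1_A = m1[, 1], pool1_C = m1[, 2], pool1_G = m1[, 3],
      pool1_T = m1[, 4], pool1_N = 0L, pool1_del = 0L,
      pool2_A = m2[, 1], pool2_C = m2[, 2], pool2_G = m2[, 3],
      pool2_T = m2[, 4], pool2_N = 0L, pool2_del = 0L)
    truth <- tibble::tibble(pos = as.integer(pos), sex_linked = sexlinked,
                            ref = ref, alt = alt,
                            freq_alt_pool1 = f1, freq_alt_pool2 = f2)
    structure(list(counts = counts, truth = truth), class = "pool_sim")
  })
}

#' Long-read error model
#'
#' Error injection walks the template once; each base independently suffers
#' an error with probability `error_rate`, split by `mix` into substitution
#' (a uniformly chosen other base), insertion (a random base inserted next
#' to the template base) or deletion (the base dropped). The default total
#' rate 0.0644 and the lognormal read-length distribution describe a
#' nanopore-like profile.
#'
#' @param error_rate total per-base error probability. Default 0.0644.
#' @param mix length-3 proportions (substitution, insertion, deletion)
#'   summing to 1.
#' @param length_meanlog,length_sdlog lognormal read-length parameters.
#' @param length_min minimum read length (truncation), bp.
#' @param seed integer seed.
#' @return object of class `long_read_error_model`.
#' @export
long_read_error_model <- function(error_rate = 0.0644,
                                  mix = c(sub = 0.4, ins = 0.3, del = 0.3),
                                  length_meanlog = log(8000),
                                  length_sdlog = 0.5,
                                  length_min = 1000, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1, length(mix) == 3,
            abs(sum(mix) - 1) < 1e-8, length_min >= 1)
  structure(list(error_rate = error_rate, mix = mix,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 length_min = length_min, seed = seed),
            class = "long_read_error_model")
}

inject_read_errors <- function(template, model) {
  b <- strsplit(template, "", fixed = TRUE)[[1]]
  m <- length(b)
  err <- which(runif(m) < model$error_rate)
  if (length(err) == 0) return(template)
  type <- sample(c("S", "I", "D"), length(err), replace = TRUE,
                 prob = model$mix)
  out <- b
  is_s <- err[type == "S"]
  if (length(is_s)) out[is_s] <- other_base(b[is_s])
  is_d <- err[type == "D"]
  if (length(is_d)) out[is_d] <- ""
  is_i <- err[type == "I"]
  if (length(is_i))
    out[is_i] <- paste0(sample(BASES, length(is_i), replace = TRUE), b[is_i])
  paste(out, collapse = "")
}

#' Simulate long reads from a haplotype with an error model
#'
#' Reads start uniformly along the haplotype; read ids are opaque (they
#' encode nothing about origin) and the truth table carries provenance.
#'
#' @param haplotype source sequence (string or an object carrying one).
#' @param n number of reads; 0 gives empty output.
#' @param model a [long_read_error_model()].
#' @param origin label recorded in the truth table (e.g. "X" or "Y").
#' @param id_prefix prefix for generated read ids.
#' @return list of class `longread_sim` with `reads` (tibble: `read_id`,
#'   `seq`) and `truth` (tibble: `read_id`, `origin`, `start`, `end` of the
#'   error-free source interval).
#' @export
simulate_long_reads <- function(haplotype, n, model = long_read_error_model(),
                                origin = "unknown", id_prefix = "read") {
  sq <- as_sequence(haplotype)
  L <- nchar(sq)
  stopifnot(n >= 0, inherits(model, "long_read_error_model"))
  if (model$length_min > L)
    stop("length_min exceeds haplotype length", call. = FALSE)
  if (n == 0)
    return(structure(list(
      reads = tibble::tibble(read_id = character(), seq = character()),
      truth = tibble::tibble(read_id = character(), origin = character(),
                             start = integer(), end = integer())),
      class = "longread_sim"))
  local_seed(model$seed, {
    len <- pmin(pmax(round(rlnorm(n, model$length_meanlog, model$length_sdlog)),
                     model$length_min), L)
    start <- vapply(len, function(l) sample.int(L - l + 1L, 1L), 0L)
    end <- start + len - 1L
    tmpl <- substring(sq, start, end)
    seqs <- vapply(tmpl, inject_read_errors, character(1), model = model,
                   USE.NAMES = FALSE)
    ids <- sprintf("%s_%05d", id_prefix, seq_len(n))
    structure(list(
      reads = tibble::tibble(read_id = ids, seq = seqs),
      truth = tibble::tibble(read_id = ids, origin = origin,
                             start = as.integer(start), end = as.integer(end))),
      class = "longread_sim")
  })
}
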