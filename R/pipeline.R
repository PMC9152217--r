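#' Preset pipeline configurations
#'
#' Three presets mirror the study designs this package addresses:
#' `"koka-like"` and `"kpandu-like"` simulate an XY population whose males
#' carry the duplication-based Y (reads from both haplotypes, a planted
#' sex-linked window), `"hora-like"` a population with no sex-linked
#' region on the scanned chromosome (no Y haplotype, no Y-origin reads).
#'
#' @param preset preset name.
#' @param seed integer seed (mandatory: runs are reproducible by
#'   construction).
#' @param scale "desk" (default; small region, fast) or "full".
#' @return a `pipeline_config` list.
#' @export
preset_config <- function(preset = c("koka-like", "kpandu-like",
                                     "hora-like"),
                          seed, scale = c("desk", "full")) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  stopifnot(is.numeric(seed), length(seed) == 1)
  has_y <- preset != "hora-like"
  n_reads <- if (scale == "desk") c(x = 20, y = 12) else c(x = 60, y = 30)
  # scanned chromosome much longer than the sex region, so that truly
  # sex-linked windows stay a small fraction of all windows and the
  # empirical enrichment null is meaningful
  region_len <- if (scale == "desk") 260000L else 1300000L
  validate_pipeline_config(list(
    preset = preset, seed = as.integer(seed), scale = scale,
    region_length = region_len, gc = 0.41,
    pool = list(n_per_sex = 10, depth_mean = 170, seq_error = 0.002,
                snp_density = 1, sexlinked_snp_density = 5,
                sex_system = if (has_y) "XY" else "none",
                subsample_fraction = 0.2),
    scan = list(window_size = if (scale == "desk") 2000 else 10000),
    long_reads = list(error_rate = 0.0644,
                      length_meanlog = log(if (scale == "desk") 4000
                                           else 8000),
                      length_sdlog = 0.2, length_min = 1000),
    n_reads_x = unname(n_reads["x"]),
    n_reads_y = if (has_y) unname(n_reads["y"]) else 0,
    classify = list(trim = 23, min_hit_score = 60, flank = 200, tol = 30),
    consensus = list(min_depth = 2, agreement_threshold = 0.6)))
}

#' Run the full two-pronged workflow on synthetic data
#'
#' Executes simulate -> scan and build-Y -> classify -> consensus under one
#' seed: generates the reference and (for XY presets) the true Y, simulates
#' pooled counts and long reads, runs the pooled sex-SNP scan, builds the
#' expected Y, classifies reads by the diagnostic deletion and calls a
#' backbone consensus from the Y-specific subset. Fully reproducible from
#' (config, seed); rerunning with the same config yields an identical
#' summary.
#'
#' @param config a `pipeline_config` ([preset_config()] /
#'   [read_pipeline_config()]) or a preset name (then `seed` is required).
#' @param seed used when `config` is a preset name.
#' @return object of class `pipeline_report`: list with `scan`
#'   ([scan_sex_snps()] result), `classification` ([classify_reads()]
#'   result), `consensus` (or NULL if no Y-specific reads), `truth`,
#'   `summary` (flat named list) and `summary_json` (deterministic
#'   machine-readable summary).
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) {
    if (is.null(seed)) stop("preset runs need a seed", call. = FALSE)
    config <- preset_config(config, seed = seed)
  }
  cfg <- validate_pipeline_config(config)
  scale <- cfg$scale %||% "desk"
  seed <- cfg$seed

  genes <- default_gene_models(scale)
  yspec <- default_y_spec(scale)
  ref <- generate_reference(cfg$region_length %||% default_region_length(scale),
                            genes, gc = cfg$gc %||% 0.41, seed = seed)
  has_y <- (cfg$pool$sex_system %||% "XY") == "XY"

  # pooled scan arm
  pool_cfg <- do.call(pool_sim_config,
                      modifyList(cfg$pool %||% list(),
                                 list(seed = seed + 1L)))
  sim <- simulate_pool_counts(ref, pool_cfg,
                              sex_region = if (has_y) yspec$dup_source)
  scan_cfg <- do.call(scan_config, cfg$scan %||% list())
  scan <- scan_sex_snps(sim$counts, scan_cfg)
  enriched <- enriched_windows(scan)

  # long-read arm
  model <- build_expected_y(ref, genes, yspec)
  truey <- if (has_y) make_true_y(ref, yspec)
  lr_args <- cfg$long_reads %||% list()
  # long reads are locus-proximal (the genome-wide bait subset has already
  # happened upstream in a real dataset); sampling from a prefix window
  # around the duplication keeps coordinates identical to the full
  # haplotype while concentrating reads on the region of interest
  x_window <- min(nchar(ref$seq), yspec$dup_source[2] + 6000L)
  reads_x <- simulate_long_reads(
    substr(ref$seq, 1, x_window), cfg$n_reads_x %||% 20,
    do.call(long_read_error_model, modifyList(lr_args, list(seed = seed + 2L))),
    origin = "X", id_prefix = "rx")
  reads_y <- if (has_y && (cfg$n_reads_y %||% 0) > 0) {
    copy_len <- nchar(truey$y_seq) - nchar(ref$seq)
    y_window <- min(nchar(truey$y_seq),
                    yspec$dup_insert_at + copy_len + 6000L)
    simulate_long_reads(
      substr(truey$y_seq, 1, y_window), cfg$n_reads_y,
      do.call(long_read_error_model, modifyList(lr_args, list(seed = seed + 3L))),
      origin = "Y", id_prefix = "ry")
  }
  reads <- if (is.null(reads_y)) reads_x$reads
  else dplyr::bind_rows(reads_x$reads, reads_y$reads)
  truth_reads <- if (is.null(reads_y)) reads_x$truth
  else dplyr::bind_rows(reads_x$truth, reads_y$truth)

  baits <- prepare_baits(genes, ref)
  cl_args <- cfg$classify %||% list()
  classification <- classify_reads(
    reads, ref, yspec, baits = baits,
    trim = cl_args$trim %||% 23,
    min_hit_score = cl_args$min_hit_score %||% 60,
    flank = cl_args$flank %||% 200, tol = cl_args$tol %||% 30)

  # consensus from the Y-specific subset onto the expected-Y backbone
  ylab <- classification$calls$read_id[
    classification$calls$label == "Y-specific"]
  consensus <- NULL
  if (length(ylab) > 0) {
    yreads <- reads[reads$read_id %in% ylab, , drop = FALSE]
    stack <- stack_alignments(yreads, model)
    cons_args <- cfg$consensus %||% list()
    consensus <- do.call(call_consensus, c(list(stack), cons_args))
  }

  g <- glance.sexscan(scan)
  lab <- classification$labels
  summary <- list(
    preset = cfg$preset %||% "custom", seed = seed, scale = scale,
    n_sites = g$n_sites, n_candidates = g$n_candidates,
    n_windows = g$n_windows, n_enriched_windows = nrow(enriched),
    top_window_start = g$top_window_start,
    top_window_candidates = g$top_window_candidates,
    n_reads = nrow(reads),
    n_bait_pass = classification$n_bait_pass,
    n_y_specific = as.integer(lab[["Y-specific"]]),
    n_non_y = as.integer(lab[["non-Y"]]),
    n_unassigned = as.integer(lab[["unassigned"]]),
    consensus_length = if (is.null(consensus)) 0L
    else nchar(consensus$sequence),
    consensus_ambiguous = if (is.null(consensus)) NA_integer_
    else consensus$n_ambiguous)
  structure(list(config = cfg, scan = scan, enriched_windows = enriched,
                 model = model, classification = classification,
                 consensus = consensus,
                 truth = list(pool = sim$truth, reads = truth_reads),
                 summary = summary,
                 summary_json = jsonlite::toJSON(summary, auto_unbox = TRUE,
                                                 digits = NA)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report> preset:", s$preset, "seed:", s$seed, "\n")
  cat("  scan:", s$n_sites, "sites,", s$n_candidates, "candidates,",
      s$n_enriched_windows, "enriched window(s)\n")
  cat("  reads:", s$n_reads, "in,", s$n_bait_pass, "bait-passing;",
      "Y-specific:", s$n_y_specific, "non-Y:", s$n_non_y,
      "unassigned:", s$n_unassigned, "\n")
  if (s$consensus_length > 0)
    cat("  consensus:", s$consensus_length, "bp,",
        s$consensus_ambiguous, "ambiguous column(s)\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `pipeline_report`.
#' @param ... unused.
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble::as_tibble(x$summary[!vapply(x$summary, is.null, TRUE)])
}
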