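# Default synthetic region layouts. The full scale mirrors the studied
# system: a ~51 kb tandem duplication carrying dot1l / oaz1 / a linked
# hormone-pathway gene ("amh") with a 275 bp Y-diagnostic deletion in the
# truncated oaz1 copy, two large (>5 kb) deletions fusing the dot1l and
# oaz1 copies into a chimera, and an amh copy carrying a 5 bp exon-6
# insertion plus a 233 bp exon-7 deletion. The desk scale is a smaller
# layout with the same qualitative structure for fast tests.

#' Default gene models for the synthetic sex region
#'
#' @param scale "full" (60 kb reference, 51 kb duplication) or "desk"
#'   (20 kb reference, 12 kb duplication).
#' @return gene-model tibble; the dot1l-like gene carries a masked
#'   vasa-like intron, the amh-like gene carries 7 exons.
#' @export
default_gene_models <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    amh_start <- 28001L
    amh_exons <- tibble::tibble(
      start = amh_start + (0:6) * 500L,
      end = amh_start + (0:6) * 500L + 299L)
    dplyr::bind_rows(
      gene_model("dot1l", 6001, 15000,
                 exons = tibble::tibble(start = c(6001, 9001, 12001),
                                        end = c(7000, 10500, 15000)),
                 masked = tibble::tibble(start = 7001, end = 9000)),
      gene_model("oaz1", 17001, 21000),
      gene_model("loc_linked", 23001, 26000),
      gene_model("amh", amh_start, 31300, exons = amh_exons))
  } else {
    amh_start <- 10001L
    amh_exons <- tibble::tibble(
      start = amh_start + (0:6) * 250L,
      end = amh_start + (0:6) * 250L + 149L)
    dplyr::bind_rows(
      gene_model("dot1l", 2501, 6500,
                 exons = tibble::tibble(start = c(2501, 3801),
                                        end = c(3000, 6500)),
                 masked = tibble::tibble(start = 3001, end = 3800)),
      gene_model("oaz1", 7501, 9500),
      gene_model("amh", amh_start, 11650, exons = amh_exons))
  }
}

#' Default Y structural-variant specification
#'
#' Full scale: a 51 kb tandem duplication (source 5001-56000, inserted at
#' 56001) whose copy carries two applied >5 kb deletions - one fusing the
#' dot1l and oaz1 copies into a chimera - the always-applied 275 bp
#' diagnostic deletion in the truncated oaz1 copy, and the amh-copy edits
#' (5 bp insertion in exon 6, 233 bp deletion in exon 7; both under the
#' 500 bp keep threshold, so present on the true Y but retained in the
#' expected Y). Desk scale: a 12 kb duplication with a 275 bp diagnostic
#' deletion and scaled-down amh-copy edits, no large deletions.
#'
#' @inheritParams default_gene_models
#' @return a [y_variant_spec()].
#' @export
default_y_spec <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    y_variant_spec(
      dup_source = c(5001, 56000),
      dup_insert_at = 56001,
      deletions = tibble::tibble(
        start = c(12001L, 40001L, 31050L),
        end = c(18000L, 46500L, 31282L)),
      insertions = tibble::tibble(at = 30650L, seq = "TTCAG"),
      diagnostic_deletion = c(19001, 19275))
  } else {
    y_variant_spec(
      dup_source = c(2001, 14000),
      dup_insert_at = 14001,
      deletions = tibble::tibble(start = 11511L, end = 11630L),
      insertions = tibble::tibble(at = 11300L, seq = "TTCAG"),
      diagnostic_deletion = c(8300, 8574))
  }
}

#' Default reference length per scale
#' @inheritParams default_gene_models
#' @return length in bp.
#' @export
default_region_length <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  if (scale == "full") 60000L else 20000L
}
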