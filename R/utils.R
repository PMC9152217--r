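# shared helpers: seeded RNG scope, sequence utilities, interval checks

BASES <- c("A", "C", "G", "T")

IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed uses (and advances) the current stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(length, gc = 0.41) {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  if (length == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of A/C/G/T sequences (case preserved per base).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0) return("")
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# substitute other-base uniformly for substitution errors
other_base <- function(base) {
  idx <- match(base, BASES)
  off <- sample.int(3L, length(base), replace = TRUE)
  BASES[((idx - 1L + off) %% 4L) + 1L]
}

check_interval <- function(iv, lo, hi, what = "interval") {
  if (length(iv) != 2 || anyNA(iv) || iv[1] > iv[2])
    stop(what, " must be c(start, end) with start <= end", call. = FALSE)
  if (iv[1] < lo || iv[2] > hi)
    stop(what, " [", iv[1], ", ", iv[2], "] outside [", lo, ", ", hi, "]",
         call. = FALSE)
  invisible(iv)
}

intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# extract sequence from objects carrying one (plain string, ref, or model)
as_sequence <- function(x) {
  if (is.character(x) && length(x) == 1) return(x)
  if (inherits(x, "ref_haplotype")) return(x$seq)
  if (inherits(x, "haplotype_model")) return(x$y_seq)
  if (inherits(x, "y_haplotype")) return(x$y_seq)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a sequence", call. = FALSE)
}

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC[key]
  if (is.na(code)) "N" else unname(code)
}
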