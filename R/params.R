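#' Detection parameters for the fixed-penalty microsatellite search
#'
#' Bundles the scoring configuration of the imperfect-microsatellite
#' detector. A repeat tract of length `L` base pairs carrying `m` motif
#' mismatches receives the score `L - mismatch_penalty * m` and is reported
#' when the score reaches `min_score`. Candidate tracts are grown from
#' perfect seed repeats; a seed is a maximal perfect tandem run of a
#' primitive motif with at least `seed_min_copies` full copies and at least
#' `seed_min_len` bp, or any perfect run already reaching `min_score` bp
#' (so that perfect loci of every motif size at or above the score
#' threshold are always seeded).
#'
#' @param min_score Integer score threshold; a locus is reported when
#'   `length - mismatch_penalty * n_mismatches >= min_score`. Default 15.
#' @param mismatch_penalty Integer penalty per motif mismatch. Default 5.
#' @param max_consecutive_mm Maximum number of consecutive mismatch
#'   positions allowed inside a tract. Default (and conventional value) 3.
#' @param motif_lens Integer vector of motif lengths to search, a subset of
#'   `1:6` (mono- through hexanucleotide).
#' @param seed_min_copies Minimum number of full motif copies in a perfect
#'   seed run. Default 3.
#' @param seed_min_len Minimum seed run length in bp. Default 8.
#'
#' @return An object of class `detection_params` (a named list).
#' @examples
#' detection_params()
#' detection_params(min_score = 10, mismatch_penalty = 5)
#' @export
detection_params <- function(min_score = 15L, mismatch_penalty = 5L,
                             max_consecutive_mm = 3L, motif_lens = 1:6,
                             seed_min_copies = 3L, seed_min_len = 8L) {
  min_score <- as.integer(min_score)
  mismatch_penalty <- as.integer(mismatch_penalty)
  max_consecutive_mm <- as.integer(max_consecutive_mm)
  motif_lens <- sort(unique(as.integer(motif_lens)))
  seed_min_copies <- as.integer(seed_min_copies)
  seed_min_len <- as.integer(seed_min_len)
  if (min_score < 1L) stop("min_score must be >= 1")
  if (mismatch_penalty < 1L) stop("mismatch_penalty must be >= 1")
  if (max_consecutive_mm < 0L) stop("max_consecutive_mm must be >= 0")
  if (length(motif_lens) == 0L || !all(motif_lens %in% 1:6)) {
    stop("motif_lens must be a non-empty subset of 1:6")
  }
  if (seed_min_copies < 1L || seed_min_len < 1L) {
    stop("seed_min_copies and seed_min_len must be >= 1")
  }
  structure(
    list(min_score = min_score, mismatch_penalty = mismatch_penalty,
         max_consecutive_mm = max_consecutive_mm, motif_lens = motif_lens,
         seed_min_copies = seed_min_copies, seed_min_len = seed_min_len),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Microsatellite detection parameters\n")
  cat(sprintf("  min score            : %d\n", x$min_score))
  cat(sprintf("  mismatch penalty     : %d\n", x$mismatch_penalty))
  cat(sprintf("  max consecutive mism.: %d\n", x$max_consecutive_mm))
  cat(sprintf("  motif lengths        : %s\n",
              paste(x$motif_lens, collapse = ",")))
  cat(sprintf("  seed: >= %d copies and >= %d bp (or >= %d bp perfect)\n",
              x$seed_min_copies, x$seed_min_len, x$min_score))
  invisible(x)
}

# minimal perfect-run length that makes a seed for motif length k:
# run >= seed_min_len and (>= seed_min_copies full copies or >= min_score bp)
seed_need <- function(k, params) {
  max(params$seed_min_len,
      min(params$seed_min_copies * k, params$min_score))
}
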