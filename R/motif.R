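#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number power of a shorter
#' string (e.g. `"ACAC"` is `"AC"^2` and therefore not primitive).
#'
#' @param motif Character vector of motifs.
#' @return Logical vector.
#' @examples
#' is_primitive_motif(c("AC", "ACAC", "AAG", "AA"))
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(TRUE)
    ch <- strsplit(m, "", fixed = TRUE)[[1]]
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L && all(ch == rep_len(ch[seq_len(d)], k))) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonical (standardized) motif
#'
#' Returns the representative of a motif's equivalence class under cyclic
#' rotation and reverse complementation: the lexicographically smallest
#' string among all rotations of the motif and all rotations of its
#' reverse complement. Repeats on opposite strands or in different tract
#' phases therefore share one `std_motif` and can be grouped into motif
#' classes.
#'
#' @param motif Character vector of primitive motifs over `A,C,G,T`,
#'   lengths 1-6.
#' @return Character vector of canonical motifs; the function is
#'   idempotent.
#' @examples
#' standardize_motif(c("TG", "GAA", "A")) # "AC", "AAG", "A"
#' @export
standardize_motif <- function(motif) {
  if (any(grepl("[^ACGT]", motif))) {
    stop("motifs must be over A,C,G,T")
  }
  if (!all(is_primitive_motif(motif))) {
    stop("motif is not primitive")
  }
  vapply(motif, function(m) {
    k <- nchar(m)
    rots <- function(s) {
      d <- paste0(s, s)
      vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), character(1))
    }
    min(c(rots(m), rots(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

# rotate a motif (character vector of single bases) so that its phase
# starts at 0-based offset `shift` of the original
rotate_motif_chars <- function(motif_ch, shift) {
  k <- length(motif_ch)
  motif_ch[((shift + 0:(k - 1L)) %% k) + 1L]
}
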