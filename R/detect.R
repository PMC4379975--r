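# Seed-and-extend detection of perfect and imperfect microsatellites
# under the fixed-penalty scoring model: score = L - penalty * mismatches,
# reported when score >= min_score and no more than max_consecutive_mm
# consecutive mismatch positions occur inside the tract. Tracts always
# begin and end on a matching position and never contain N.

#' Fixed-penalty locus score
#'
#' @param L Tract length in bp.
#' @param m Number of motif mismatches in the tract.
#' @param params [detection_params()].
#' @return Integer score `L - mismatch_penalty * m`.
#' @examples
#' locus_score(20, 1) # 15 under the default penalty of 5
#' @export
locus_score <- function(L, m, params = detection_params()) {
  if (any(L < 1) || any(m < 0)) stop("need L >= 1 and m >= 0")
  as.integer(L) - params$mismatch_penalty * as.integer(m)
}

#' Find perfect seed repeats
#'
#' Reports every maximal perfect tandem run of a primitive motif of length
#' `k` that qualifies as a seed: at least `seed_min_copies` full copies and
#' at least `seed_min_len` bp, or at least `min_score` bp (a perfect run
#' already reaching the score threshold is always a seed). Runs never span
#' an `N`.
#'
#' @param seq A single nucleotide sequence (character scalar).
#' @param k Motif length.
#' @param params [detection_params()].
#' @return Data.frame with columns `start`, `end` (0-based half-open) and
#'   `motif` (observed unit at the run start).
#' @export
find_seeds <- function(seq, k, params = detection_params()) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  find_seeds_chr(s, as.integer(k), params)
}

find_seeds_chr <- function(s, k, params) {
  empty <- data.frame(start = integer(), end = integer(),
                      motif = character(), stringsAsFactors = FALSE)
  n <- length(s)
  need <- seed_need(k, params)
  if (n < need || n <= k) return(empty)
  a <- s[seq_len(n - k)]
  b <- s[(k + 1L):n]
  ok <- (a == b) & a != "N" & b != "N"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & (r$lengths + k) >= need)
  if (length(hit) == 0L) return(empty)
  st <- starts[hit]           # 1-based start of the tandem region
  en <- ends[hit] + k         # 1-based inclusive end
  motif <- vapply(st, function(i) {
    paste(s[i:(i + k - 1L)], collapse = "")
  }, character(1))
  keep <- is_primitive_motif(motif)
  data.frame(start = st[keep] - 1L, end = en[keep], motif = motif[keep],
             stringsAsFactors = FALSE)
}

# Scan outward from `from` in direction `dir` (+1/-1) under the phase
# anchored at `anchor1` with motif characters `motif_ch`; stop before an N,
# the sequence end, or the position completing a run of more than `cap`
# consecutive mismatches. Returns the last included position (1-based).
scan_boundary <- function(s, from, dir, anchor1, motif_ch, cap) {
  k <- length(motif_ch)
  n <- length(s)
  j <- from
  consec <- 0L
  last <- from - dir
  while (j >= 1L && j <= n) {
    if (s[j] == "N") break
    if (s[j] == motif_ch[((j - anchor1) %% k) + 1L]) {
      consec <- 0L
    } else {
      consec <- consec + 1L
      if (consec > cap) break
    }
    last <- j
    j <- j + dir
  }
  last
}

#' Extend a seed into a (possibly imperfect) microsatellite candidate
#'
#' The seed is grown outwards position-by-position against the
#' phase-expected motif base. Mismatches are absorbed as long as no more
#' than `max_consecutive_mm` occur in a row; `N` and the sequence ends are
#' hard boundaries. The extended window is then trimmed so that both tract
#' ends are matching positions and the score `L - penalty * m` is maximal
#' over all admissible trims (ties resolved towards the longer tract).
#'
#' @param seq A single nucleotide sequence (character scalar).
#' @param seed One-row data.frame or list with `start`, `end` (0-based
#'   half-open) and `motif`, as returned by [find_seeds()].
#' @param params [detection_params()].
#' @return A one-row data.frame candidate with 0-based half-open `start`,
#'   `end`, tract-phase `motif`, `motif_len`, `length`, `n_mismatches`,
#'   `mismatch_positions` (list column, 0-based within-tract offsets) and
#'   `score`, or `NULL` when the best trim scores below `min_score`.
#' @export
extend_seed <- function(seq, seed, params = detection_params()) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  extend_seed_chr(s, as.integer(seed$start) + 1L, as.integer(seed$end),
                  seed$motif, params)
}

# anchor1/seed_end1: 1-based inclusive seed coordinates
extend_seed_chr <- function(s, anchor1, seed_end1, motif, params) {
  motif_ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  k <- length(motif_ch)
  cap <- params$max_consecutive_mm
  p <- params$mismatch_penalty
  wl <- scan_boundary(s, anchor1 - 1L, -1L, anchor1, motif_ch, cap)
  wr <- scan_boundary(s, seed_end1 + 1L, +1L, anchor1, motif_ch, cap)
  idx <- wl:wr
  expd <- motif_ch[((idx - anchor1) %% k) + 1L]
  mm <- s[idx] != expd
  T_ <- length(idx)
  seedl <- anchor1 - wl + 1L    # window-relative seed bounds
  seedr <- seed_end1 - wl + 1L
  cm <- cumsum(mm)              # mismatches in 1..t
  cmb <- c(0L, cm)              # cmb[t] = mismatches in 1..t-1
  # left trim: new start t (a match position at or before the seed start)
  cand_t <- which(!mm[seq_len(seedl)])
  gl <- p * cmb[cand_t] - (cand_t - 1L)
  t <- cand_t[which.max(gl)]    # first max -> smallest trim -> longer tract
  # right trim: new end u (a match position at or after the seed end)
  cand_u <- which(!mm)
  cand_u <- cand_u[cand_u >= seedr]
  gr <- p * (cm[T_] - cm[cand_u]) - (T_ - cand_u)
  u <- cand_u[max(which(gr == max(gr)))]
  m <- cm[u] - cmb[t]
  L <- u - t + 1L
  score <- L - p * m
  if (score < params$min_score) return(NULL)
  start0 <- wl + t - 2L         # 0-based
  end0 <- wl + u - 1L           # 0-based half-open
  tract_motif <- paste(rotate_motif_chars(motif_ch,
                                          (start0 + 1L - anchor1) %% k),
                       collapse = "")
  out <- data.frame(start = start0, end = end0, motif = tract_motif,
                    motif_len = k, length = L, n_mismatches = as.integer(m),
                    score = as.integer(score), stringsAsFactors = FALSE)
  out$mismatch_positions <- list(which(mm[t:u]) - 1L)
  out
}

# Greedy overlap resolution: higher score first, then smaller motif
# length, then leftmost start, then longer tract; nested/partial overlaps
# are discarded in that order.
resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  o <- order(-cand$score, cand$motif_len, cand$start, -cand$end, cand$motif)
  cand <- cand[o, , drop = FALSE]
  kept_start <- integer(0)
  kept_end <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < kept_end & cand$end[i] > kept_start)) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, cand$start[i])
      kept_end <- c(kept_end, cand$end[i])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Detect perfect and imperfect microsatellites
#'
#' Scans one or more sequences for microsatellites of all configured motif
#' lengths using the seed-and-extend strategy, scores tracts with the
#' fixed-penalty rule and resolves overlapping candidates greedily (higher
#' score, then smaller motif length, then leftmost start). Output is
#' deterministic for fixed input and parameters.
#'
#' @param seqs Named character vector of sequences (an assembly), a
#'   `DNAStringSet`, or a single unnamed sequence (then named `"seq1"`).
#' @param params [detection_params()].
#' @param assembly Optional assembly identifier stored as provenance.
#' @return A locus table: data.frame with class `locus_table`, one row per
#'   reported locus, 0-based half-open `start`/`end`, tract-phase `motif`,
#'   canonical `std_motif`, `motif_len`, `length`, `n_mismatches`,
#'   `mismatch_positions` (list column of 0-based offsets), `score` and
#'   `is_perfect`, sorted by (chrom, start). Attributes `assembly` and
#'   `params` record provenance.
#' @examples
#' detect_microsatellites(c(chr1 = "TTACACACACACACACACTT"))
#' @export
detect_microsatellites <- function(seqs, params = detection_params(),
                                   assembly = NA_character_) {
  if (is.character(seqs) && is.null(names(seqs)) && length(seqs) == 1L) {
    names(seqs) <- "seq1"
  }
  seqs <- normalize_assembly(seqs)
  per_chrom <- lapply(names(seqs), function(chrom) {
    s <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
    cand_list <- list()
    for (k in params$motif_lens) {
      seeds <- find_seeds_chr(s, k, params)
      for (i in seq_len(nrow(seeds))) {
        cnd <- extend_seed_chr(s, seeds$start[i] + 1L, seeds$end[i],
                               seeds$motif[i], params)
        if (!is.null(cnd)) cand_list[[length(cand_list) + 1L]] <- cnd
      }
    }
    if (length(cand_list) == 0L) return(NULL)
    cand <- do.call(rbind, cand_list)
    cand <- cand[!duplicated(paste(cand$start, cand$end, cand$motif)), ,
                 drop = FALSE]
    kept <- resolve_overlaps(cand)
    kept$chrom <- chrom
    kept
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
  if (length(per_chrom) == 0L) {
    return(new_locus_table(assembly = assembly, params = params))
  }
  all <- do.call(rbind, per_chrom)
  new_locus_table(chrom = all$chrom, start = all$start, end = all$end,
                  motif = all$motif,
                  mismatch_positions = all$mismatch_positions,
                  score = all$score, assembly = assembly, params = params)
}
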