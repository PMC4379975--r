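# Independent brute-force reference detector used to validate
# detect_microsatellites(). It enumerates, for every primitive motif
# realized as at least one clean full copy in the sequence and for every
# phase, all substrings whose ends are matching positions, that contain
# no run of more than max_consecutive_mm consecutive mismatches and no N,
# and whose fixed-penalty score reaches the threshold; overlaps are then
# resolved by the same published rule (score desc, motif length asc,
# leftmost start, longer tract). No seeding or extension heuristics are
# involved.

oracle_candidates_chrom <- function(s, params) {
  n <- length(s)
  S <- params$min_score
  p <- params$mismatch_penalty
  cap <- params$max_consecutive_mm
  out <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in params$motif_lens) {
    if (n < max(k, S)) next
    for (i in seq_len(n - k + 1L)) {
      motif_ch <- s[i:(i + k - 1L)]
      if (any(motif_ch == "N")) next
      motif <- paste(motif_ch, collapse = "")
      if (!is_primitive_motif(motif)) next
      key <- paste(k, i %% k, motif)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      expd <- motif_ch[(((1:n) - i) %% k) + 1L]
      mm <- s != expd
      blocked <- s == "N"
      v <- ifelse(blocked, 2L, as.integer(mm))
      r <- rle(v)
      rends <- cumsum(r$lengths)
      rstarts <- rends - r$lengths + 1L
      bad <- blocked
      for (ri in which(r$values == 1L & r$lengths > cap)) {
        bad[rstarts[ri]:rends[ri]] <- TRUE
      }
      rs <- rle(!bad)
      sends <- cumsum(rs$lengths)
      sstarts <- sends - rs$lengths + 1L
      for (si in which(rs$values & rs$lengths >= S)) {
        a <- sstarts[si]
        b <- sends[si]
        rel_mm <- mm[a:b]
        mp <- which(!rel_mm)
        if (length(mp) == 0L) next
        cm0 <- c(0L, cumsum(rel_mm))
        mm_at <- which(rel_mm)
        for (ss in mp) {
          ee <- mp[mp >= ss + S - 1L]
          if (length(ee) == 0L) next
          L <- ee - ss + 1L
          m <- cm0[ee + 1L] - cm0[ss]
          sc <- L - p * m
          ok <- sc >= S
          if (!any(ok)) next
          ee <- ee[ok]
          start0 <- a + ss - 2L
          shift <- (start0 + 1L - i) %% k
          mot <- paste(motif_ch[((shift + 0:(k - 1L)) %% k) + 1L],
                       collapse = "")
          chunk <- data.frame(
            start = rep(start0, length(ee)), end = a + ee - 1L,
            motif = mot, motif_len = k, length = L[ok],
            n_mismatches = as.integer(m[ok]),
            score = as.integer(sc[ok]), stringsAsFactors = FALSE)
          chunk$mismatch_positions <- lapply(ee, function(e) {
            as.integer(mm_at[mm_at >= ss & mm_at <= e] - ss)
          })
          out[[length(out) + 1L]] <- chunk
        }
      }
    }
  }
  if (length(out) == 0L) {
    e <- data.frame(start = integer(), end = integer(), motif = character(),
                    motif_len = integer(), length = integer(),
                    n_mismatches = integer(), score = integer(),
                    stringsAsFactors = FALSE)
    e$mismatch_positions <- list()
    return(e)
  }
  do.call(rbind, out)
}

oracle_greedy <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  o <- order(-cand$score, cand$motif_len, cand$start, -cand$end, cand$motif)
  cand <- cand[o, , drop = FALSE]
  ks <- integer(0)
  ke <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < ke & cand$end[i] > ks)) {
      keep[i] <- TRUE
      ks <- c(ks, cand$start[i])
      ke <- c(ke, cand$end[i])
    }
  }
  cand[keep, , drop = FALSE]
}

oracle_detect <- function(seqs, params = detection_params()) {
  rows <- lapply(names(seqs), function(chrom) {
    s <- strsplit(toupper(seqs[[chrom]]), "", fixed = TRUE)[[1]]
    cand <- oracle_candidates_chrom(s, params)
    if (nrow(cand) == 0L) return(NULL)
    cand <- cand[!duplicated(paste(cand$start, cand$end, cand$motif)), ,
                 drop = FALSE]
    kept <- oracle_greedy(cand)
    kept$chrom <- chrom
    kept
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    e <- data.frame(chrom = character(), start = integer(), end = integer(),
                    motif = character(), n_mismatches = integer(),
                    stringsAsFactors = FALSE)
    e$mismatch_positions <- list()
    e$score <- integer()
    return(e)
  }
  all <- do.call(rbind, rows)
  all <- all[order(all$chrom, all$start),
             c("chrom", "start", "end", "motif", "n_mismatches",
               "mismatch_positions", "score")]
  rownames(all) <- NULL
  all
}

# strip a locus table to the fields the oracle reports, for comparison
comparable_loci <- function(table) {
  df <- as.data.frame(table)[, c("chrom", "start", "end", "motif",
                                 "n_mismatches", "mismatch_positions",
                                 "score")]
  df$mismatch_positions <- lapply(df$mismatch_positions, as.integer)
  rownames(df) <- NULL
  df
}

# Random test sequence, optionally with an embedded repeat tract drawn
# from the same family the synthetic-genome generator emulates: imperfect
# tracts arising from point mutations of a once-perfect repeat, which
# always retain a perfect stretch long enough to seed the search.
random_ssr_sequence <- function(min_len = 60L, max_len = 200L,
                                p_plant = 0.5,
                                params = detection_params()) {
  n <- sample(min_len:max_len, 1L)
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (stats::runif(1) < p_plant) {
    motif <- sample(c("A", "AT", "AC", "AG", "AAG", "AGC", "ACGT",
                      "AACGT", "AACGTC"), 1L)
    k <- nchar(motif)
    m <- sample(0:3, 1L)
    lmin <- params$min_score + params$mismatch_penalty * m + 2L
    if (lmin > n - 2L) m <- 0L
    lmin <- max(16L, params$min_score + params$mismatch_penalty * m + 2L)
    L <- sample(lmin:max(lmin, min(60L, n - 2L)), 1L)
    tr <- rep_len(strsplit(motif, "", fixed = TRUE)[[1]], L)
    if (m > 0L) {
      off <- imssr:::sample_mismatch_offsets(L, k, m, params)
      for (o in off) {
        tr[o + 1L] <- sample(setdiff(c("A", "C", "G", "T"), tr[o + 1L]), 1L)
      }
    }
    at <- sample.int(n - L + 1L, 1L)
    s[at:(at + L - 1L)] <- tr
    # sharpen the tract boundaries (as the genome generator does): the
    # two adjacent background bases disagree with the phase-expected
    # continuation of the repeat
    motif_ch <- strsplit(motif, "", fixed = TRUE)[[1]]
    for (d in c(-2L, -1L, L, L + 1L)) {
      j <- at + d                     # 1-based genome position
      if (j >= 1L && j <= n) {
        exp_b <- motif_ch[(d %% k) + 1L]
        s[j] <- sample(setdiff(c("A", "C", "G", "T"), exp_b), 1L)
      }
    }
  }
  paste(s, collapse = "")
}
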