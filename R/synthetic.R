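# Seeded synthetic genomes, SNP tables and haplotype panels with planted
# ground truth. Everything is a pure function of its spec (including the
# seed), so every downstream module can be validated without external
# data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(restore_rng(old))
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")

#' Describe a microsatellite tract to plant in a synthetic genome
#'
#' Either give explicit mismatch offsets (a fully determined tract) or
#' just a mismatch count, in which case admissible offsets are sampled at
#' genome-generation time. Sampled offsets are constrained so that the
#' planted tract is recovered exactly by the detector whenever its score
#' reaches the threshold: mismatches keep clear of the tract ends far
#' enough that no end-trim improves the score, they never run longer than
#' the consecutive-mismatch cap, and at least one perfect stretch long
#' enough to seed the search is left intact (mirroring the mutational
#' origin of imperfect repeats as point mutations in a once-perfect
#' tract).
#'
#' @param motif Primitive repeat unit (1-6 bp over A,C,G,T).
#' @param length Tract length in bp (need not be a whole number of motif
#'   copies).
#' @param n_mismatches Number of mismatches to sample (ignored when
#'   `mismatch_offsets` is given).
#' @param mismatch_offsets Optional explicit 0-based within-tract offsets.
#' @param mismatch_bases Optional substituted bases (must differ from the
#'   phase-expected base); chosen deterministically when omitted.
#' @return List of class `planted_locus`.
#' @export
planted_locus <- function(motif, length, n_mismatches = 0L,
                          mismatch_offsets = NULL, mismatch_bases = NULL) {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif) || !is_primitive_motif(motif)) {
    stop("motif must be primitive over A,C,G,T")
  }
  length <- as.integer(length)
  if (length < nchar(motif)) stop("tract shorter than its motif")
  if (!is.null(mismatch_offsets)) {
    mismatch_offsets <- sort(as.integer(mismatch_offsets))
    if (any(mismatch_offsets < 0L) || any(mismatch_offsets >= length)) {
      stop("mismatch offsets out of tract range")
    }
    if (anyDuplicated(mismatch_offsets)) stop("duplicate mismatch offsets")
    n_mismatches <- base::length(mismatch_offsets)
  }
  structure(list(motif = motif, length = length,
                 n_mismatches = as.integer(n_mismatches),
                 mismatch_offsets = mismatch_offsets,
                 mismatch_bases = mismatch_bases),
            class = "planted_locus")
}

# phase-expected base of a planted tract at 0-based offset
expected_base <- function(motif_ch, offset) {
  motif_ch[(offset %% length(motif_ch)) + 1L]
}

#' Realize the nucleotide sequence of a planted tract
#'
#' @param pl A [planted_locus()] with explicit mismatch offsets.
#' @return Character scalar: the tract sequence.
#' @export
tract_sequence <- function(pl) {
  motif_ch <- strsplit(pl$motif, "", fixed = TRUE)[[1]]
  s <- rep_len(motif_ch, pl$length)
  off <- pl$mismatch_offsets
  if (is.null(off) && pl$n_mismatches > 0L) {
    stop("mismatch offsets not yet sampled; use generate_genome()")
  }
  if (length(off)) {
    bases <- pl$mismatch_bases
    if (is.null(bases)) {
      bases <- vapply(off, function(o) {
        setdiff(BASES, expected_base(motif_ch, o))[1]
      }, character(1))
    }
    if (any(bases == s[off + 1L])) {
      stop("a substituted base equals the phase-expected base")
    }
    s[off + 1L] <- bases
  }
  paste(s, collapse = "")
}

# longest run of non-mismatch positions in a tract of length L with
# mismatches at 0-based `off`
longest_clean_run <- function(L, off) {
  bounds <- c(-1L, sort(off), L)
  max(diff(bounds) - 1L)
}

# admissibility of a planted mismatch-offset set: end-trim-proof, within
# the consecutive cap, and seedable
offsets_admissible <- function(off, L, k, params) {
  if (length(off) == 0L) return(TRUE)
  off <- sort(off)
  m <- length(off)
  p <- params$mismatch_penalty
  j <- seq_len(m)
  if (any(off < p * j - 1L)) return(FALSE)
  if (any((L - 1L - rev(off)) < p * j - 1L)) return(FALSE)
  runs <- rle(diff(off) == 1L)
  if (any(runs$values & runs$lengths + 1L > params$max_consecutive_mm)) {
    return(FALSE)
  }
  longest_clean_run(L, off) >= seed_need(k, params)
}

sample_mismatch_offsets <- function(L, k, m, params, max_try = 2000L) {
  if (m == 0L) return(integer())
  for (i in seq_len(max_try)) {
    off <- sort(sample.int(L - 2L, m))  # offsets in 1..L-2 (0-based)
    if (offsets_admissible(off, L, k, params)) return(off)
  }
  stop(sprintf(
    "could not place %d mismatches admissibly in a %d bp tract of %d-mer motif",
    m, L, k))
}

# what the detector reports for the isolated tract: "exact" (one locus
# spanning the full tract with the planted mismatches), "absent", or
# "partial"
isolated_detection <- function(tract, pl, params) {
  res <- detect_microsatellites(c(x = paste0("NN", tract, "NN")), params)
  if (nrow(res) == 0L) return("absent")
  off <- if (is.null(pl$mismatch_offsets)) integer() else pl$mismatch_offsets
  if (nrow(res) == 1L && res$start == 2L && res$end == 2L + pl$length &&
      identical(res$mismatch_positions[[1]], as.integer(off))) {
    return("exact")
  }
  "partial"
}

#' Specification of a synthetic genome with planted repeat tracts
#'
#' @param seed Integer seed; the generated genome is a pure function of
#'   the spec including this seed.
#' @param length Genome length in bp.
#' @param planted List of [planted_locus()] objects.
#' @param min_spacing Minimum distance in bp between planted tracts
#'   (default 50).
#' @param base_probs Background base composition, named probabilities for
#'   A,C,G,T (default uniform).
#' @param id Sequence identifier of the synthetic chromosome.
#' @param params [detection_params()] that detectability is defined
#'   against.
#' @return List of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(seed, length = 10000L, planted = list(),
                                  min_spacing = 50L,
                                  base_probs = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                                  id = "synth1",
                                  params = detection_params()) {
  if (!all(sort(names(base_probs)) == BASES) || any(base_probs < 0) ||
      abs(sum(base_probs) - 1) > 1e-8) {
    stop("base_probs must be probabilities named A,C,G,T summing to 1")
  }
  if (!all(vapply(planted, inherits, logical(1), "planted_locus"))) {
    stop("planted must be a list of planted_locus objects")
  }
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 planted = planted, min_spacing = as.integer(min_spacing),
                 base_probs = base_probs[BASES], id = id, params = params),
            class = "synthetic_genome_spec")
}

random_background <- function(n, base_probs) {
  if (n <= 0L) return(character(0))
  sample(BASES, n, replace = TRUE, prob = base_probs)
}

#' Generate a synthetic genome with planted ground truth
#'
#' Plants the specified tracts at randomly spaced, non-overlapping
#' positions (separated by at least `min_spacing` bp) in random background
#' sequence. The two background bases adjacent to each tract are forced to
#' disagree with the tract's phase-expected continuation so that tract
#' boundaries are sharp, and the whole background is rejection-sampled
#' against the detector: if any planted, detectable tract is not recovered
#' exactly, or any unplanted tract is detected, the background is redrawn.
#' False-positive and recovery tests on the output are therefore exact
#' rather than probabilistic. Deterministic for a fixed spec.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return List of class `synthetic_genome` with elements `genome` (named
#'   character vector of length 1), `truth` (locus table of every planted
#'   tract, with an extra logical column `detectable`), and `spec`.
#' @export
generate_genome <- function(spec) {
  if (!inherits(spec, "synthetic_genome_spec")) {
    stop("need a synthetic_genome_spec")
  }
  params <- spec$params
  with_seed(spec$seed, {
    planted <- lapply(spec$planted, function(pl) {
      if (is.null(pl$mismatch_offsets) && pl$n_mismatches > 0L) {
        for (i in seq_len(200L)) {
          off <- sample_mismatch_offsets(pl$length, nchar(pl$motif),
                                         pl$n_mismatches, params)
          cand <- planted_locus(pl$motif, pl$length, mismatch_offsets = off)
          if (isolated_detection(tract_sequence(cand), cand, params) !=
              "partial") {
            return(cand)
          }
        }
        stop("could not realize planted locus without partial detection")
      }
      if (is.null(pl$mismatch_offsets)) {
        pl$mismatch_offsets <- integer()
      }
      pl
    })
    tracts <- vapply(planted, tract_sequence, character(1))
    status <- vapply(seq_along(planted), function(i) {
      isolated_detection(tracts[i], planted[[i]], params)
    }, character(1))
    if (any(status == "partial")) {
      stop("planted locus would be detected only partially; ",
           "adjust its mismatch offsets")
    }
    n_loci <- length(planted)
    lens <- vapply(planted, `[[`, integer(1), "length")
    edge <- 10L
    free <- spec$length - sum(lens) -
      (if (n_loci > 1L) (n_loci - 1L) * spec$min_spacing else 0L) - 2L * edge
    if (n_loci > 0L && free < 0L) {
      stop("planted loci do not fit in the genome with the required spacing")
    }
    # random gap sizes on top of the minimum spacing
    extra <- if (n_loci > 0L) {
      as.integer(stats::rmultinom(1L, free, rep(1, n_loci + 1L)))
    } else integer()
    gaps <- if (n_loci > 0L) {
      c(edge, rep(spec$min_spacing, max(0L, n_loci - 1L)), edge) + extra
    } else spec$length
    starts0 <- if (n_loci > 0L) {
      cumsum(c(0L, lens)) [seq_len(n_loci)] + cumsum(gaps[seq_len(n_loci)])
    } else integer()
    draw <- function() {
      s <- character(spec$length)
      pos <- 1L
      for (i in seq_len(n_loci)) {
        gap <- gaps[i]
        s[pos:(pos + gap - 1L)] <- random_background(gap, spec$base_probs)
        pos <- pos + gap
        tr <- strsplit(tracts[i], "", fixed = TRUE)[[1]]
        s[pos:(pos + lens[i] - 1L)] <- tr
        pos <- pos + lens[i]
      }
      if (pos <= spec$length) {
        s[pos:spec$length] <- random_background(spec$length - pos + 1L,
                                                spec$base_probs)
      }
      # sharpen tract boundaries: flanking bases disagree with the
      # phase-expected continuation
      for (i in seq_len(n_loci)) {
        motif_ch <- strsplit(planted[[i]]$motif, "", fixed = TRUE)[[1]]
        g0 <- starts0[i]
        for (d in c(-2L, -1L, lens[i], lens[i] + 1L)) {
          j <- g0 + d            # 0-based genome position
          if (j >= 0L && j < spec$length) {
            exp_b <- expected_base(motif_ch, d)
            s[j + 1L] <- sample(setdiff(BASES, exp_b), 1L)
          }
        }
      }
      paste(s, collapse = "")
    }
    truth <- new_locus_table(
      chrom = rep(spec$id, n_loci),
      start = starts0,
      end = starts0 + lens,
      motif = vapply(planted, `[[`, character(1), "motif"),
      mismatch_positions = lapply(planted, `[[`, "mismatch_offsets"),
      score = lens - params$mismatch_penalty *
        vapply(planted, `[[`, integer(1), "n_mismatches"),
      assembly = spec$id, params = params)
    # truth rows come out sorted by start; align auxiliary vectors
    ord <- order(starts0)
    truth$detectable <- (status[ord] == "exact")
    expected <- truth[truth$detectable, , drop = FALSE]
    genome <- NULL
    for (attempt in seq_len(60L)) {
      g <- draw()
      det <- detect_microsatellites(stats::setNames(g, spec$id), params,
                                    assembly = spec$id)
      same <- nrow(det) == nrow(expected) &&
        all(det$start == expected$start) && all(det$end == expected$end) &&
        all(det$motif == expected$motif) &&
        identical(lapply(det$mismatch_positions, as.integer),
                  lapply(expected$mismatch_positions, as.integer))
      if (same) {
        genome <- g
        break
      }
    }
    if (is.null(genome)) {
      stop("could not sample a background free of spurious detections")
    }
    structure(list(genome = stats::setNames(genome, spec$id),
                   truth = truth, spec = spec),
              class = "synthetic_genome")
  })
}

#' Plant SNPs inside synthetic microsatellite tracts
#'
#' Places `n_snps` SNPs at positions inside the detectable planted tracts
#' of a synthetic genome. Each SNP is planted as type M1 with probability
#' `q` (its position is a mismatch offset of an imperfect tract and its
#' alleles are the assembly base there plus the phase-consensus base, both
#' represented in the motif variants) and otherwise as type M0 (its
#' alternate allele is drawn from outside the variant set at its phase).
#' REF is always the assembly base. Positions are unique.
#'
#' @param sg A `synthetic_genome` from [generate_genome()].
#' @param n_snps Number of SNPs to plant.
#' @param q Probability that a SNP is planted as M1 (in \[0, 1\]).
#' @param seed Integer seed.
#' @return SNP data.frame as from [read_snp_table()] with an extra column
#'   `truth_class` (`"M0"`/`"M1"`).
#' @export
generate_snps <- function(sg, n_snps = 100L, q = 0.5, seed = 1L) {
  if (!inherits(sg, "synthetic_genome")) stop("need a synthetic_genome")
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  truth <- sg$truth
  det <- truth[truth$detectable, , drop = FALSE]
  imp <- det[det$n_mismatches > 0L, , drop = FALSE]
  if (nrow(det) == 0L) stop("no detectable planted loci to carry SNPs")
  if (q > 0 && nrow(imp) == 0L) {
    stop("M1 SNPs need at least one imperfect detectable locus")
  }
  genome <- sg$genome[[1]]
  chrom <- names(sg$genome)
  with_seed(seed, {
    used <- integer(0)
    out <- vector("list", n_snps)
    for (i in seq_len(n_snps)) {
      want_m1 <- stats::runif(1) < q
      for (try in seq_len(500L)) {
        if (want_m1) {
          li <- imp[sample.int(nrow(imp), 1L), , drop = FALSE]
          o <- sample(rep(li$mismatch_positions[[1]], 2L), 1L)
        } else {
          li <- det[sample.int(nrow(det), 1L), , drop = FALSE]
          o <- sample.int(li$length, 1L) - 1L
        }
        pos <- li$start + o + 1L
        if (pos %in% used) next
        k <- li$motif_len
        motif_ch <- strsplit(li$motif, "", fixed = TRUE)[[1]]
        phase <- o %% k
        ref <- substr(genome, pos, pos)
        mm_off <- li$mismatch_positions[[1]]
        same_phase <- mm_off[mm_off %% k == phase]
        variant_set <- unique(c(motif_ch[phase + 1L],
                                vapply(same_phase, function(oo) {
                                  substr(genome, li$start + oo + 1L,
                                         li$start + oo + 1L)
                                }, character(1))))
        if (want_m1) {
          alt <- setdiff(variant_set, ref)
          if (length(alt) == 0L) next
          alt <- alt[1]
        } else {
          pool <- setdiff(BASES, unique(c(variant_set, ref)))
          if (length(pool) == 0L) next
          alt <- sample(rep(pool, 2L), 1L)
        }
        used <- c(used, pos)
        row <- data.frame(chrom = chrom, pos = pos,
                          snp_id = sprintf("rs%06d", i), ref = ref,
                          truth_class = if (want_m1) "M1" else "M0",
                          stringsAsFactors = FALSE)
        row$alts <- list(alt)
        out[[i]] <- row
        break
      }
      if (is.null(out[[i]])) {
        stop("could not place SNP ", i, " (tracts saturated); ",
             "reduce n_snps or plant more loci")
      }
    }
    res <- do.call(rbind, out)
    res[order(res$pos), c("chrom", "pos", "snp_id", "ref", "alts",
                          "truth_class")]
  })
}

#' Generate an inbred-line haplotype panel from a synthetic genome
#'
#' Produces `n_lines` copies of the synthetic genome with independent
#' random substitutions at per-site rates that may differ inside and
#' outside the planted tracts, recording every introduced mutation.
#'
#' @param sg A `synthetic_genome` from [generate_genome()].
#' @param n_lines Number of lines (default 29, a typical inbred-panel
#'   size).
#' @param sub_rate_in Per-site substitution probability inside planted
#'   tracts.
#' @param sub_rate_out Per-site substitution probability outside tracts.
#' @param seed Integer seed.
#' @return List with `panel` (a [haplotype_panel()], reference = the
#'   synthetic genome) and `mutations` (data.frame with `line`, `pos`
#'   (1-based), `ref`, `alt`, `in_tract`).
#' @export
generate_panel <- function(sg, n_lines = 29L, sub_rate_in = 0.005,
                           sub_rate_out = 0.001, seed = 1L) {
  if (!inherits(sg, "synthetic_genome")) stop("need a synthetic_genome")
  genome_ch <- strsplit(sg$genome[[1]], "", fixed = TRUE)[[1]]
  n <- length(genome_ch)
  in_tract <- logical(n)
  for (i in seq_len(nrow(sg$truth))) {
    in_tract[(sg$truth$start[i] + 1L):sg$truth$end[i]] <- TRUE
  }
  rate <- ifelse(in_tract, sub_rate_in, sub_rate_out)
  with_seed(seed, {
    lines <- character(n_lines)
    muts <- list()
    for (l in seq_len(n_lines)) {
      hit <- which(stats::runif(n) < rate)
      s <- genome_ch
      for (j in hit) {
        s[j] <- sample(setdiff(BASES, genome_ch[j]), 1L)
      }
      lines[l] <- paste(s, collapse = "")
      if (length(hit)) {
        muts[[l]] <- data.frame(line = sprintf("line%02d", l), pos = hit,
                                ref = genome_ch[hit], alt = s[hit],
                                in_tract = in_tract[hit],
                                stringsAsFactors = FALSE)
      }
    }
    names(lines) <- sprintf("line%02d", seq_len(n_lines))
    mutations <- if (length(muts)) do.call(rbind, muts) else
      data.frame(line = character(), pos = integer(), ref = character(),
                 alt = character(), in_tract = logical())
    list(panel = haplotype_panel(sg$genome, lines), mutations = mutations)
  })
}

#' Simulate points for the mismatch-on-M1 regression
#'
#' Draws M1-mutation counts and mismatch burdens from a linear model with
#' a planted percent-effect: the slope is chosen so that one M1 mutation
#' changes the mismatch burden by `percent_effect` percent of the mean
#' response, then Gaussian noise is added.
#'
#' @param n Number of loci (points).
#' @param percent_effect Planted per-mutation effect in percent of the
#'   mean mismatch burden (default 56).
#' @param intercept Mean mismatch burden at zero M1 mutations (default 4).
#' @param sigma Gaussian noise standard deviation (default 0.5).
#' @param seed Integer seed.
#' @return List with `points` (data.frame `m1_count`, `n_mismatches`),
#'   `true_slope` and `true_percent_effect`.
#' @export
simulate_m1_regression <- function(n = 500L, percent_effect = 56,
                                   intercept = 4, sigma = 0.5, seed = 1L) {
  with_seed(seed, {
    x <- stats::rbinom(n, 2L, 0.25)   # 0-2 accumulated M1 mutations
    mean_x <- 0.5
    pe <- percent_effect / 100
    slope <- -pe * intercept / (1 + pe * mean_x)
    y <- intercept + slope * x + stats::rnorm(n, 0, sigma)
    list(points = data.frame(m1_count = x, n_mismatches = y),
         true_slope = slope,
         true_percent_effect = percent_effect)
  })
}
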