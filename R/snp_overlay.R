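# Overlay SNPs on detected microsatellites, classify loci as M0/M1 by
# whether all SNP alleles are represented among the bases realized at the
# SNP's motif phase, and test association between allele patterns and
# mismatch burden with Yates' continuity-corrected chi-square.

#' Map SNPs onto microsatellite loci
#'
#' Intersects 1-based SNP positions with the tracts of a locus table and
#' computes, for each overlap, the 0-based offset of the SNP within the
#' tract, the phase-expected (consensus) base at that offset, the assembly
#' base, and the set of bases realized at the SNP's motif phase (the
#' consensus base plus the assembly base at every mismatch offset of the
#' locus sharing that phase). SNPs outside all loci are dropped; their
#' number is recorded in the `n_unmapped` attribute.
#'
#' @param snps SNP data.frame as from [read_snp_table()].
#' @param table Locus table from the same assembly.
#' @param seqs The assembly (named character vector); used to verify that
#'   each mapped SNP's REF allele equals the assembly base (a mismatch is
#'   a data-inconsistency error).
#' @return Data.frame of overlaps with columns `snp_id`, `chrom`, `pos`,
#'   `ref`, `alts` (list), `locus_row` (row index into `table`), `offset`
#'   (0-based within tract), `phase_base`, `ref_base`, `variant_set`
#'   (list of bases realized at the SNP's phase), plus locus columns
#'   `locus_length` and `locus_n_mismatches`; attribute `n_unmapped`.
#' @export
map_snps_to_loci <- function(snps, table, seqs) {
  seqs <- normalize_assembly(seqs)
  validate_locus_table(table)
  rows <- list()
  n_unmapped <- 0L
  for (i in seq_len(nrow(snps))) {
    chrom <- snps$chrom[i]
    pos <- snps$pos[i]
    hit <- which(table$chrom == chrom & table$start < pos & pos <= table$end)
    if (length(hit) == 0L) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    if (is.na(match(chrom, names(seqs)))) {
      stop("SNP chromosome not in assembly: ", chrom)
    }
    base <- substr(seqs[[chrom]], pos, pos)
    if (base != snps$ref[i]) {
      stop(sprintf(
        "SNP %s: REF allele %s disagrees with assembly base %s at %s:%d",
        snps$snp_id[i], snps$ref[i], base, chrom, pos))
    }
    for (h in hit) {
      offset <- pos - 1L - table$start[h]
      k <- table$motif_len[h]
      motif_ch <- strsplit(table$motif[h], "", fixed = TRUE)[[1]]
      phase <- offset %% k
      mm_off <- table$mismatch_positions[[h]]
      same_phase <- mm_off[mm_off %% k == phase]
      mm_bases <- if (length(same_phase)) {
        vapply(same_phase, function(o) {
          substr(seqs[[chrom]], table$start[h] + o + 1L,
                 table$start[h] + o + 1L)
        }, character(1))
      } else character(0)
      row <- data.frame(
        snp_id = snps$snp_id[i], chrom = chrom, pos = pos,
        ref = snps$ref[i], locus_row = h, offset = offset,
        phase_base = motif_ch[phase + 1L], ref_base = base,
        locus_length = table$length[h],
        locus_n_mismatches = table$n_mismatches[h],
        stringsAsFactors = FALSE)
      row$alts <- list(snps$alts[[i]])
      row$variant_set <- list(unique(c(motif_ch[phase + 1L], mm_bases)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), chrom = character(), pos = integer(),
               ref = character(), locus_row = integer(), offset = integer(),
               phase_base = character(), ref_base = character(),
               locus_length = integer(), locus_n_mismatches = integer(),
               alts = I(list()), variant_set = I(list()))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Classify SNP-in-microsatellite overlaps as M0 or M1
#'
#' A locus/SNP pair is of type M1 when every SNP allele (REF and all ALTs)
#' is represented among the bases realized at the SNP's motif phase within
#' the tract -- the phase-expected consensus base plus the assembly base at
#' every mismatch offset sharing that phase. Otherwise it is M0: the SNP
#' introduces a base not present in the motif variants. For a perfect
#' locus the variant set is the consensus base alone, so any biallelic SNP
#' is M0. The verdict does not depend on the order of ALT alleles.
#'
#' @param overlaps Data.frame from [map_snps_to_loci()].
#' @return The input with added columns `verdict` (`"M0"`/`"M1"`) and
#'   `allele_set` (list of REF plus ALT alleles).
#' @export
classify_m0_m1 <- function(overlaps) {
  allele_set <- lapply(seq_len(nrow(overlaps)), function(i) {
    sort(unique(c(overlaps$ref[i], overlaps$alts[[i]])))
  })
  verdict <- vapply(seq_len(nrow(overlaps)), function(i) {
    if (all(allele_set[[i]] %in% overlaps$variant_set[[i]])) "M1" else "M0"
  }, character(1))
  overlaps$verdict <- verdict
  overlaps$allele_set <- allele_set
  overlaps
}

#' Build the M0/M1 x mismatch-class contingency table
#'
#' Cross-tabulates classified SNP-locus overlaps into a 2x2 table with
#' rows M0/M1 and columns `lt3` (< `mm_threshold` mismatches) / `ge3`
#' (>= threshold), restricted to loci of length at least `min_length` bp
#' (length control). By default each overlap (SNP classification) counts
#' once; `locus_level = TRUE` collapses multiple SNPs in one locus to the
#' majority verdict (ties to M0).
#'
#' @param classified Data.frame from [classify_m0_m1()].
#' @param min_length Minimum tract length in bp (default 30).
#' @param mm_threshold Mismatch-count threshold (default 3).
#' @param locus_level Collapse to one verdict per locus (default FALSE).
#' @return 2x2 integer matrix, rows `c("M0","M1")`, columns
#'   `c("lt3","ge3")`.
#' @export
build_contingency <- function(classified, min_length = 30L,
                              mm_threshold = 3L, locus_level = FALSE) {
  keep <- classified[classified$locus_length >= min_length, , drop = FALSE]
  tab <- matrix(0L, 2L, 2L, dimnames = list(c("M0", "M1"),
                                            c("lt3", "ge3")))
  if (nrow(keep) == 0L) return(tab)
  if (locus_level) {
    by_locus <- split(seq_len(nrow(keep)), keep$locus_row)
    verdict <- vapply(by_locus, function(ix) {
      v <- keep$verdict[ix]
      if (sum(v == "M1") > sum(v == "M0")) "M1" else "M0"
    }, character(1))
    mm <- vapply(by_locus, function(ix) keep$locus_n_mismatches[ix[1]],
                 integer(1))
  } else {
    verdict <- keep$verdict
    mm <- keep$locus_n_mismatches
  }
  col <- ifelse(mm < mm_threshold, "lt3", "ge3")
  for (i in seq_along(verdict)) {
    tab[verdict[i], col[i]] <- tab[verdict[i], col[i]] + 1L
  }
  tab
}

#' Yates' continuity-corrected chi-square for a 2x2 table
#'
#' `chi2 = N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`
#' with the p-value from the chi-square distribution on 1 degree of
#' freedom. The corrected statistic never exceeds the uncorrected one and
#' is invariant under transposition and row/column swaps.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return List of class `chi2_result`: `chi2`, `df` (1), `p_value`.
#' @examples
#' yates_chi2(matrix(c(10, 20, 20, 10), 2, byrow = TRUE)) # chi2 = 5.4
#' @export
yates_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    stop("need a 2x2 table of non-negative counts")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (N == 0 || any(margins == 0)) {
    stop("zero margin: Yates chi-square undefined")
  }
  chi2 <- N * max(0, abs(a * d - b * c_) - N / 2)^2 / prod(margins)
  structure(list(chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE)),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("Yates chi-square = %.4g, df = 1, p = %.4g\n",
              x$chi2, x$p_value))
  invisible(x)
}
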