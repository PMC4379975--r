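# Population-panel utilities: polymorphic microsatellite loci across
# inbred lines, regression of mismatch burden on M1-type mutation
# accumulation, and generation-to-year conversion.

#' Construct a haplotype panel
#'
#' A substitution-only panel: every line sequence has the same length as
#' the reference and is aligned to it by construction (no indels), so
#' tract intervals detected on the reference can be read directly from
#' each line.
#'
#' @param reference Named character vector of length 1 (the reference
#'   interval).
#' @param lines Named character vector of line sequences, all of the
#'   reference length.
#' @return List of class `haplotype_panel` with elements `ref_id`,
#'   `ref_seq`, `lines`.
#' @export
haplotype_panel <- function(reference, lines) {
  reference <- normalize_assembly(reference)
  if (length(reference) != 1L) stop("reference must be a single sequence")
  lines <- normalize_assembly(lines)
  if (any(nchar(lines) != nchar(reference))) {
    stop("all line sequences must equal the reference length ",
         "(substitution-only panel)")
  }
  structure(list(ref_id = names(reference), ref_seq = unname(reference),
                 lines = lines),
            class = "haplotype_panel")
}

#' Find polymorphic microsatellite loci across a panel of lines
#'
#' Detects microsatellites on the reference sequence, extracts the same
#' interval from every line, and reports loci where at least two distinct
#' tract sequences segregate, together with the 0-based within-tract
#' offsets of the segregating sites. The result is invariant to line
#' order, and adding a line identical to an existing one never changes it.
#'
#' @param panel A [haplotype_panel()].
#' @param params [detection_params()].
#' @return Data.frame with the reference-locus columns (`start`, `end`,
#'   `motif`, `length`, `n_mismatches`), `n_distinct_alleles`,
#'   `segregating_offsets` (list column) and `tract_seqs` (list column of
#'   named per-line tract strings, reference included as `"ref"`).
#' @export
find_polymorphic_loci <- function(panel, params = detection_params()) {
  if (!inherits(panel, "haplotype_panel")) stop("need a haplotype_panel")
  ref <- stats::setNames(panel$ref_seq, panel$ref_id)
  loci <- detect_microsatellites(ref, params, assembly = panel$ref_id)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    s1 <- loci$start[i] + 1L
    s2 <- loci$end[i]
    tracts <- c(ref = substr(panel$ref_seq, s1, s2),
                vapply(panel$lines, substr, character(1), s1, s2))
    alleles <- unique(unname(tracts))
    if (length(alleles) < 2L) next
    chars <- do.call(rbind, strsplit(unname(tracts), "", fixed = TRUE))
    seg <- which(apply(chars, 2, function(col) length(unique(col)) > 1L)) - 1L
    row <- data.frame(start = loci$start[i], end = loci$end[i],
                      motif = loci$motif[i], length = loci$length[i],
                      n_mismatches = loci$n_mismatches[i],
                      n_distinct_alleles = length(alleles),
                      stringsAsFactors = FALSE)
    row$segregating_offsets <- list(as.integer(seg))
    row$tract_seqs <- list(tracts)
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    out <- data.frame(start = integer(), end = integer(),
                      motif = character(), length = integer(),
                      n_mismatches = integer(),
                      n_distinct_alleles = integer(),
                      segregating_offsets = I(list()),
                      tract_seqs = I(list()))
    return(out)
  }
  do.call(rbind, rows)
}

#' Regress mismatch burden on M1-type mutation accumulation
#'
#' Ordinary least squares of the per-locus mismatch count on the number of
#' accumulated M1-type mutations. The effect is also reported as a
#' percentage of the mean response: `percent_effect = 100 * |slope| /
#' mean(response)`, the per-mutation relative change in mismatch burden.
#'
#' @param points Data.frame with columns `m1_count` (predictor) and
#'   `n_mismatches` (response), at least 3 rows, non-degenerate
#'   predictor.
#' @return List of class `m1_regression`: `slope`, `intercept`,
#'   `percent_effect`, `p_value` (of the slope), `n`, and the fitted `lm`
#'   object as `model`.
#' @export
regress_mismatch_on_m1 <- function(points) {
  if (!all(c("m1_count", "n_mismatches") %in% names(points))) {
    stop("points needs columns m1_count and n_mismatches")
  }
  if (nrow(points) < 3L) stop("need >= 3 points")
  if (stats::var(points$m1_count) == 0) {
    stop("degenerate predictor: m1_count has no variance")
  }
  fit <- stats::lm(n_mismatches ~ m1_count, data = points)
  coefs <- summary(fit)$coefficients
  slope <- coefs["m1_count", "Estimate"]
  structure(list(
    slope = slope,
    intercept = coefs["(Intercept)", "Estimate"],
    percent_effect = 100 * abs(slope) / mean(points$n_mismatches),
    p_value = coefs["m1_count", "Pr(>|t|)"],
    n = nrow(points),
    model = fit
  ), class = "m1_regression")
}

#' @export
print.m1_regression <- function(x, ...) {
  cat(sprintf(
    "OLS: mismatches = %.3f %+.3f * m1_count (p = %.3g, n = %d)\n",
    x$intercept, x$slope, x$p_value, x$n))
  cat(sprintf("One M1 mutation changes mismatch burden by %.1f%% of the mean\n",
              x$percent_effect))
  invisible(x)
}

#' Convert generations to whole years
#'
#' `floor(g * days_per_generation / days_per_year)`. The truncating
#' conversion with 365.25 days per year is used so that a generation count
#' maps to the number of complete years elapsed. The default generation
#' time of 36 days is the conventional average for *Drosophila
#' melanogaster*.
#'
#' @param g Number of generations (>= 0); vectorized.
#' @param days_per_generation Average generation time in days (default
#'   36).
#' @param days_per_year Days per year (default 365.25).
#' @return Integer vector of whole years.
#' @examples
#' generations_to_years(c(1380, 1530)) # 136, 150
#' @export
generations_to_years <- function(g, days_per_generation = 36,
                                 days_per_year = 365.25) {
  if (any(g < 0)) stop("g must be >= 0")
  if (days_per_generation <= 0 || days_per_year <= 0) {
    stop("generation time and year length must be positive")
  }
  as.integer(floor(g * days_per_generation / days_per_year))
}
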