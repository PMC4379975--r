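# Genome-level mismatch statistics: summaries, the per-site mismatch
# rate, the observed-versus-expected mismatch partition, abundance
# matrices for multivariate tests, and correlation helpers.

#' Summarize microsatellite content of one genome
#'
#' @param table Locus table from one assembly.
#' @param genome_size Genome size in bp (> 0).
#' @return A list of class `genome_summary`: `genome_id`, `n_loci_total`,
#'   `n_imperfect`, `pct_imperfect` (percent of all loci that are
#'   imperfect), `total_imperfect_bp`, `pct_of_genome` (imperfect bp as
#'   percent of genome size), and per-chromosome / per-motif-length
#'   breakdown data.frames whose counts sum to the genome totals.
#' @export
summarize_genome <- function(table, genome_size) {
  if (!is.numeric(genome_size) || length(genome_size) != 1L ||
      genome_size <= 0) {
    stop("genome_size must be a single positive number")
  }
  validate_locus_table(table)
  imp <- !table$is_perfect
  n_tot <- nrow(table)
  n_imp <- sum(imp)
  per_chrom <- if (n_tot) {
    agg <- stats::aggregate(cbind(n_imperfect = imp, n_total = rep(1L, n_tot)),
                            by = list(chrom = table$chrom), FUN = sum)
    agg[order(agg$chrom), , drop = FALSE]
  } else {
    data.frame(chrom = character(), n_imperfect = integer(),
               n_total = integer())
  }
  per_k <- if (n_tot) {
    agg <- stats::aggregate(cbind(n_imperfect = imp, n_total = rep(1L, n_tot)),
                            by = list(motif_len = table$motif_len), FUN = sum)
    agg[order(agg$motif_len), , drop = FALSE]
  } else {
    data.frame(motif_len = integer(), n_imperfect = integer(),
               n_total = integer())
  }
  structure(list(
    genome_id = attr(table, "assembly"),
    n_loci_total = n_tot,
    n_imperfect = n_imp,
    pct_imperfect = if (n_tot) 100 * n_imp / n_tot else 0,
    total_imperfect_bp = sum(table$length[imp]),
    pct_of_genome = 100 * sum(table$length[imp]) / genome_size,
    per_chrom = per_chrom,
    per_motif_len = per_k
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("Genome %s: %d loci, %d imperfect (%.1f%%), %.3f%% of genome\n",
              if (is.na(x$genome_id)) "<unnamed>" else x$genome_id,
              x$n_loci_total, x$n_imperfect, x$pct_imperfect,
              x$pct_of_genome))
  invisible(x)
}

#' Genome-wide per-site mismatch rate
#'
#' The average rate of per-site mismatch: the sum of mismatch counts over
#' imperfect loci divided by the sum of their tract lengths. By default
#' only mismatch-bearing loci enter the denominator; `scope = "all"`
#' divides by the total tract length of all loci instead (a sensitivity
#' variant).
#'
#' @param table Locus table.
#' @param scope `"imperfect"` (default) or `"all"`.
#' @return The rate, a number in (0, 1).
#' @examples
#' # loci of (L = 20, m = 1) and (L = 30, m = 2): rate = 3/50 = 0.06
#' @export
mismatch_rate <- function(table, scope = c("imperfect", "all")) {
  scope <- match.arg(scope)
  imp <- !table$is_perfect
  if (!any(imp)) stop("no imperfect loci: per-site mismatch rate undefined")
  denom <- if (scope == "imperfect") sum(table$length[imp])
           else sum(table$length)
  sum(table$n_mismatches[imp]) / denom
}

#' Observed-versus-expected mismatch partition
#'
#' For each imperfect locus the expected mismatch count is `e = L * r`
#' (tract length times the genome-wide per-site mismatch rate). Loci are
#' partitioned by whether the observed count `m` is above, below, or
#' exactly equal to `e`; exact ties are reported separately so that
#' `n_higher + n_lower + n_equal` always equals the number of imperfect
#' loci.
#'
#' @param table Locus table.
#' @param r Per-site mismatch rate, typically [mismatch_rate()] of the
#'   same or a reference table.
#' @return A list of class `obs_exp_partition` with counts `n_higher`,
#'   `n_lower`, `n_equal` and a per-locus data.frame `detail` (columns
#'   `length`, `observed`, `expected`, `class`).
#' @export
obs_exp_partition <- function(table, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1) {
    stop("r must be a single rate in (0, 1)")
  }
  imp <- table[!table$is_perfect, , drop = FALSE]
  e <- imp$length * r
  cls <- ifelse(imp$n_mismatches > e, "higher",
                ifelse(imp$n_mismatches < e, "lower", "equal"))
  structure(list(
    n_higher = sum(cls == "higher"),
    n_lower = sum(cls == "lower"),
    n_equal = sum(cls == "equal"),
    detail = data.frame(length = imp$length, observed = imp$n_mismatches,
                        expected = e, class = cls,
                        stringsAsFactors = FALSE)
  ), class = "obs_exp_partition")
}

#' @export
print.obs_exp_partition <- function(x, ...) {
  cat(sprintf("Observed vs expected mismatches: %d higher, %d lower, %d equal\n",
              x$n_higher, x$n_lower, x$n_equal))
  invisible(x)
}

#' Genome-by-(length, mismatch) abundance matrix
#'
#' Counts loci per genome into cells crossing a set of tract-length levels
#' with a set of mismatch levels, the layout used by the multivariate
#' tests. A locus falls in cell (l, c) when its length equals `l` exactly
#' (optionally within `bin_width` bp) and its mismatch count equals `c`
#' (or lies in the class when `mismatch_levels` is a named list of integer
#' vectors such as `list(lt3 = 0:2, ge3 = 3:99)`).
#'
#' @param tables Named list of locus tables, one per genome.
#' @param length_levels Numeric vector of tract lengths (bp).
#' @param mismatch_levels Numeric vector of exact mismatch counts, or a
#'   named list of disjoint integer vectors defining mismatch classes.
#' @param bin_width Half-width of the length window (default 0 = exact
#'   length match).
#' @param min_length Optional minimum tract length; combined with
#'   `length_levels = NULL` this counts all loci of length `>= min_length`
#'   in one length class.
#' @return Integer matrix (genomes x cells) with a `design` attribute: a
#'   data.frame giving each column's length level and mismatch level as
#'   factors.
#' @export
abundance_matrix <- function(tables, length_levels, mismatch_levels,
                             bin_width = 0, min_length = NULL) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list (one locus table per genome)")
  }
  if (is.numeric(mismatch_levels)) {
    mm_classes <- stats::setNames(as.list(as.integer(mismatch_levels)),
                                  paste0("m", mismatch_levels))
  } else if (is.list(mismatch_levels)) {
    mm_classes <- lapply(mismatch_levels, as.integer)
    if (is.null(names(mm_classes))) stop("mismatch class list must be named")
  } else stop("mismatch_levels must be numeric or a named list")
  all_mm <- unlist(mm_classes)
  if (anyDuplicated(all_mm)) stop("mismatch classes overlap")
  use_min_len <- is.null(length_levels)
  if (use_min_len) {
    if (is.null(min_length)) stop("need length_levels or min_length")
    len_names <- paste0("ge", min_length)
    n_len <- 1L
  } else {
    if (length(length_levels) == 0L) stop("length_levels must be non-empty")
    len_names <- paste0("L", length_levels)
    n_len <- length(length_levels)
  }
  design <- expand.grid(length_level = len_names,
                        mismatch_level = names(mm_classes),
                        KEEP.OUT.ATTRS = FALSE)
  cell_names <- paste(design$length_level, design$mismatch_level, sep = ".")
  out <- matrix(0L, nrow = length(tables), ncol = nrow(design),
                dimnames = list(names(tables), cell_names))
  for (g in seq_along(tables)) {
    tb <- tables[[g]]
    for (j in seq_len(nrow(design))) {
      if (use_min_len) {
        li <- tb$length >= min_length
      } else {
        lev <- length_levels[match(design$length_level[j], len_names)]
        li <- abs(tb$length - lev) <= bin_width
      }
      mi <- tb$n_mismatches %in%
        mm_classes[[as.character(design$mismatch_level[j])]]
      out[g, j] <- sum(li & mi)
    }
  }
  design$length_level <- factor(design$length_level, levels = len_names)
  design$mismatch_level <- factor(design$mismatch_level,
                                  levels = names(mm_classes))
  attr(out, "design") <- design
  out
}

#' Pairwise correlation with explicit degeneracy handling
#'
#' Pearson product-moment correlation, or Spearman's rank correlation
#' computed as the product-moment coefficient on mid-ranks (ties receive
#' average ranks).
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @param method `"pearson"` or `"spearman"`.
#' @return The coefficient, a number in \[-1, 1\].
#' @export
pairwise_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y, method = method)
}

#' Published genome-wide imperfect-microsatellite counts for 20 insects
#'
#' Reference counts from a published genome-wide survey of imperfect
#' microsatellites in 20 insect species (searched with minimum score 15
#' and mismatch penalty 5): the number of imperfect loci per genome, the
#' percentage of all microsatellites that are imperfect, and the
#' partition of imperfect loci into those carrying more, respectively
#' fewer, mismatches than expected from the genome-wide per-site mismatch
#' rate. Species are abbreviated as genus initial plus three letters of
#' the species name (e.g. `Dmel` = *Drosophila melanogaster*).
#'
#' @return Data.frame with columns `species`, `n_imperfect`,
#'   `pct_of_all`, `n_higher`, `n_lower`.
#' @examples
#' counts <- insect_ssr_counts()
#' with(counts, pairwise_correlation(n_higher, n_lower, "spearman"))
#' @export
insect_ssr_counts <- function() {
  data.frame(
    species = c("Aaeg", "Agam", "Apis", "Cqui", "Dana", "Dere", "Dgri",
                "Dmel", "Dmoj", "Dper", "Dpse", "Dsec", "Dsim", "Dvir",
                "Dwil", "Dyak", "Amel", "Nvit", "Bmor", "Tcas"),
    n_imperfect = c(22620L, 30207L, 44563L, 20454L, 18453L, 14315L, 74637L,
                    17392L, 85525L, 40641L, 36289L, 11520L, 10995L, 62282L,
                    55121L, 17449L, 51702L, 28074L, 19732L, 5155L),
    pct_of_all = c(15.5, 28.1, 24.1, 19.5, 31.4, 36.6, 46.1, 31.6, 42.3,
                   34.6, 33.6, 28.2, 30.0, 42.8, 35.6, 35.4, 30.7, 23.4,
                   18.7, 28.8),
    n_higher = c(5596L, 14846L, 13755L, 6525L, 5766L, 5322L, 28832L, 7945L,
                 34735L, 15174L, 11947L, 4116L, 3762L, 23855L, 17832L,
                 6386L, 17893L, 12709L, 5443L, 2359L),
    n_lower = c(17024L, 15361L, 30812L, 13929L, 12687L, 8993L, 45805L,
                9447L, 50790L, 25467L, 24342L, 7404L, 7233L, 38427L,
                37289L, 11063L, 33809L, 15365L, 14289L, 2796L),
    stringsAsFactors = FALSE
  )
}
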