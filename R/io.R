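# Input/output: FASTA, minimal SNP tables, locus TSV.
#
# Coordinate conventions: in memory all tract coordinates are 0-based
# half-open; on disk they are 1-based inclusive (start_disk = start + 1,
# end_disk = end). Mismatch positions are 0-based offsets within the tract
# in memory and 1-based on disk.

# Validate and normalize an assembly: named character vector of uppercase
# A/C/G/T/N sequences with unique non-empty ids.
normalize_assembly <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be a named character vector")
  ids <- names(x)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop("every sequence must have a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence(s) contain characters other than A,C,G,T,N ",
         "(IUPAC ambiguity codes are not supported): ",
         paste(ids[bad], collapse = ", "))
  }
  x
}

#' Read a FASTA file
#'
#' Reads nucleotide sequences, folds them to uppercase and validates that
#' they contain only `A,C,G,T,N`. IUPAC ambiguity codes other than `N` are
#' rejected because the mismatch semantics of the repeat detector are
#' defined only over unambiguous bases (plus `N`, which terminates
#' tracts).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("not valid FASTA: ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path)
  x <- as.character(set)
  names(x) <- sub("\\s.*$", "", names(set))
  normalize_assembly(x)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- normalize_assembly(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Read a minimal SNP table
#'
#' Parses a 5-column tab-separated SNP table with columns CHROM, POS, ID,
#' REF, ALT (a minimal VCF dialect: no genotypes, no INFO). Lines starting
#' with `#` are ignored. ALT may list several comma-separated alleles.
#'
#' @param path Path to the table.
#' @return A data.frame with columns `chrom` (character), `pos` (integer,
#'   1-based), `snp_id` (character), `ref` (single base) and `alts`
#'   (list column of character vectors of alternate bases).
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      snp_id = character(), ref = character(),
                      alts = I(list())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 5L)) {
    stop("SNP table needs 5 tab-separated columns (CHROM POS ID REF ALT); ",
         "offending line(s): ", paste(which(n_col < 5L), collapse = ", "))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos_chr <- vapply(fields, `[[`, character(1), 2L)
  if (any(!grepl("^[0-9]+$", pos_chr)) || any(as.numeric(pos_chr) < 1)) {
    stop("POS must be a positive integer")
  }
  pos <- as.integer(pos_chr)
  snp_id <- vapply(fields, `[[`, character(1), 3L)
  ref <- toupper(vapply(fields, `[[`, character(1), 4L))
  alts <- lapply(fields, function(f) {
    toupper(strsplit(f[[5L]], ",", fixed = TRUE)[[1]])
  })
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(vapply(alts, function(a) {
        length(a) == 0L || any(!a %in% c("A", "C", "G", "T"))
      }, logical(1)))) {
    stop("REF and ALT alleles must be single bases in A,C,G,T")
  }
  bad <- mapply(function(r, a) r %in% a, ref, alts)
  if (any(bad)) {
    stop("REF allele repeated in ALT at line(s): ",
         paste(which(bad), collapse = ", "))
  }
  out <- data.frame(chrom = chrom, pos = pos, snp_id = snp_id, ref = ref,
                    stringsAsFactors = FALSE)
  out$alts <- alts
  out
}

#' Write a minimal SNP table
#'
#' Inverse of [read_snp_table()]: writes the 5-column tab-separated SNP
#' format with a `#CHROM` comment header.
#'
#' @param snps Data.frame as returned by [read_snp_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_table <- function(snps, path) {
  alt <- vapply(snps$alts, paste, character(1), collapse = ",")
  lines <- c("#CHROM\tPOS\tID\tREF\tALT",
             sprintf("%s\t%d\t%s\t%s\t%s", snps$chrom, snps$pos,
                     snps$snp_id, snps$ref, alt))
  writeLines(lines, path)
  invisible(path)
}

loci_tsv_header <- paste("chrom", "start", "end", "motif", "std_motif",
                         "motif_len", "length", "n_mismatches",
                         "mismatch_positions", "score", sep = "\t")

# Internal constructor for a locus table (0-based half-open coordinates).
new_locus_table <- function(chrom = character(), start = integer(),
                            end = integer(), motif = character(),
                            mismatch_positions = list(), score = integer(),
                            assembly = NA_character_, params = NULL) {
  k <- nchar(motif)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), motif = as.character(motif),
                   std_motif = if (length(motif)) standardize_motif(motif)
                               else character(),
                   motif_len = as.integer(k),
                   length = as.integer(end) - as.integer(start),
                   n_mismatches = as.integer(lengths(mismatch_positions)),
                   stringsAsFactors = FALSE)
  df$mismatch_positions <- lapply(mismatch_positions, as.integer)
  df$score <- as.integer(score)
  df$is_perfect <- df$n_mismatches == 0L
  if (nrow(df)) df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("locus_table", "data.frame"),
            assembly = assembly, params = params)
}

#' Validate a locus table
#'
#' Checks the structural invariants of a table of detected microsatellite
#' loci: required columns, sortedness by (chrom, start), no duplicated
#' (chrom, start, end, motif) rows, and internal consistency of length,
#' mismatch count and score.
#'
#' @param table A locus table (data.frame).
#' @param params Optional [detection_params()] used to additionally check
#'   `score = length - penalty * n_mismatches`.
#' @return Invisibly, `table`; errors on violation.
#' @export
validate_locus_table <- function(table, params = NULL) {
  need <- c("chrom", "start", "end", "motif", "std_motif", "motif_len",
            "length", "n_mismatches", "mismatch_positions", "score")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(table)) {
    o <- order(table$chrom, table$start)
    if (!identical(o, seq_len(nrow(table)))) {
      stop("rows are not sorted by (chrom, start)")
    }
    key <- paste(table$chrom, table$start, table$end, table$motif)
    if (anyDuplicated(key)) stop("duplicate (chrom, start, end, motif) rows")
    if (any(table$length != table$end - table$start)) {
      stop("length != end - start")
    }
    if (any(table$n_mismatches != lengths(table$mismatch_positions))) {
      stop("n_mismatches disagrees with mismatch_positions")
    }
    if (!is.null(params)) {
      expect <- table$length - params$mismatch_penalty * table$n_mismatches
      if (any(table$score != expect)) stop("score != length - penalty * m")
      if (any(table$score < params$min_score)) stop("score below min_score")
    }
  }
  invisible(table)
}

#' Write a locus table as TSV
#'
#' Writes one row per locus with 1-based inclusive coordinates and 1-based
#' comma-separated within-tract mismatch positions (empty for perfect
#' loci). Column order is fixed: chrom, start, end, motif, std_motif,
#' motif_len, length, n_mismatches, mismatch_positions, score. A
#' write-then-read round trip reproduces the table.
#'
#' @param table A locus table as produced by [detect_microsatellites()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_loci_tsv()]
#' @export
write_loci_tsv <- function(table, path) {
  validate_locus_table(table)
  mm <- vapply(table$mismatch_positions, function(p) {
    paste(p + 1L, collapse = ",")
  }, character(1))
  rows <- sprintf("%s\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%s\t%d",
                  table$chrom, table$start + 1L, table$end, table$motif,
                  table$std_motif, table$motif_len, table$length,
                  table$n_mismatches, mm, table$score)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  writeLines(c(loci_tsv_header, rows), con)
  invisible(path)
}

#' Read a locus table TSV
#'
#' Inverse of [write_loci_tsv()]; converts on-disk 1-based inclusive
#' coordinates back to the in-memory 0-based half-open convention.
#'
#' @param path Path to a locus TSV written by [write_loci_tsv()].
#' @return A locus table.
#' @export
read_loci_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || lines[[1L]] != loci_tsv_header) {
    stop("not a locus TSV (unexpected header)")
  }
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_locus_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[[i]] else ""
  }, character(1))
  mm <- lapply(get(9L), function(s) {
    if (!nzchar(s)) integer() else as.integer(strsplit(s, ",")[[1]]) - 1L
  })
  new_locus_table(chrom = get(1L), start = as.integer(get(2L)) - 1L,
                  end = as.integer(get(3L)), motif = get(4L),
                  mismatch_positions = mm, score = as.integer(get(10L)))
}
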