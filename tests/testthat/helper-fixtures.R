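# Shared fixture builders (everything is generated in code).

# a repeat tract as a string, with explicit mismatch offsets/bases
make_tract <- function(motif, length, offsets = integer(0), bases = NULL) {
  tract_sequence(planted_locus(motif, length, mismatch_offsets = offsets,
                               mismatch_bases = bases))
}

# flank a tract with N so that detection coordinates start at `pad`
with_n_flanks <- function(tract, pad = 2L) {
  paste0(strrep("N", pad), tract, strrep("N", pad))
}

# build a locus table directly from (chrom, start, motif, L, offsets)
# rows; score computed under `params`
make_locus_table <- function(rows, params = detection_params()) {
  imssr:::new_locus_table(
    chrom = vapply(rows, `[[`, character(1), 1),
    start = vapply(rows, `[[`, numeric(1), 2),
    end = vapply(rows, function(r) r[[2]] + r[[4]], numeric(1)),
    motif = vapply(rows, `[[`, character(1), 3),
    mismatch_positions = lapply(rows, `[[`, 5),
    score = vapply(rows, function(r) {
      r[[4]] - params$mismatch_penalty * length(r[[5]])
    }, numeric(1)),
    params = params)
}

tmpfile <- function(ext = ".txt") tempfile(fileext = ext)
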