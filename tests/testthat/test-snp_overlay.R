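# shared fixture: an AC-motif tract with known mismatches, placed at
# 0-based genome position 100
snp_fixture <- function() {
  # 40 bp AC tract at 0-based position 100; mismatches at the odd-phase
  # (consensus C) offsets 9 and 19, realized as G and T, so the odd-phase
  # variant set is {C, G, T} and the even-phase set is {A} alone
  tract <- make_tract("AC", 40, offsets = c(9L, 19L), bases = c("G", "T"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(1234)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  genome <- c(chrX = paste0(flank(100), tract, flank(60)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  table <- detect_microsatellites(genome)
  stopifnot(nrow(table) == 1L, table$start == 100L, table$end == 140L)
  list(genome = genome, table = table)
}

make_snps <- function(pos, ref, alts, chrom = "chrX") {
  df <- data.frame(chrom = chrom, pos = as.integer(pos),
                   snp_id = sprintf("rs%d", seq_along(pos)), ref = ref,
                   stringsAsFactors = FALSE)
  df$alts <- alts
  df
}

test_that("map_snps_to_loci uses 1-based inclusive tract intersection", {
  fx <- snp_fixture()
  # tract occupies 1-based 101..140; offset of pos 105 is 4
  snps <- make_snps(c(105, 141, 140, 100),
                    c("A", "T", "C", "T"),
                    list("G", "A", "T", "A"))
  ov <- map_snps_to_loci(snps, fx$table, fx$genome)
  expect_equal(ov$snp_id, c("rs1", "rs3"))
  expect_equal(ov$offset, c(4L, 39L))  # boundary base included
  expect_equal(attr(ov, "n_unmapped"), 2L)
  expect_equal(ov$phase_base, c("A", "C"))
  expect_equal(ov$ref_base, c("A", "C"))

  bad <- make_snps(105, "G", list("A"))
  expect_error(map_snps_to_loci(bad, fx$table, fx$genome), "disagrees")
})

test_that("M0/M1 verdicts follow the motif-variant sets per phase", {
  fx <- snp_fixture()
  # offset 9: assembly G (mismatch), phase consensus C; both alleles are
  # represented in the motif variants -> M1
  m1 <- make_snps(110, "G", list("C"))
  cl <- classify_m0_m1(map_snps_to_loci(m1, fx$table, fx$genome))
  expect_equal(cl$verdict, "M1")
  expect_setequal(cl$variant_set[[1]], c("C", "G", "T"))

  # same position, allele A not represented at that phase -> M0
  m0 <- make_snps(110, "G", list("A"))
  expect_equal(classify_m0_m1(
    map_snps_to_loci(m0, fx$table, fx$genome))$verdict, "M0")

  # a mismatch-free phase: variant set is the consensus alone
  p0 <- make_snps(113, "A", list("G"))
  clp <- classify_m0_m1(map_snps_to_loci(p0, fx$table, fx$genome))
  expect_equal(clp$verdict, "M0")
  expect_equal(clp$variant_set[[1]], "A")

  # verdict invariant under reordering of ALT alleles
  multi <- make_snps(c(110, 110), c("G", "G"),
                     list(c("C", "T"), c("T", "C")))
  clm <- classify_m0_m1(map_snps_to_loci(multi, fx$table, fx$genome))
  expect_equal(clm$verdict[1], clm$verdict[2])
  expect_equal(clm$verdict[1], "M1")
})

test_that("contingency table applies the length control and locus collapse", {
  cls <- data.frame(
    locus_row = c(1L, 2L, 3L),
    locus_length = c(35L, 40L, 29L),
    locus_n_mismatches = c(2L, 4L, 1L),
    verdict = c("M1", "M0", "M1"),
    stringsAsFactors = FALSE)
  tab <- build_contingency(cls)
  expect_equal(tab, matrix(c(0L, 1L, 1L, 0L), 2,
                           dimnames = list(c("M0", "M1"),
                                           c("lt3", "ge3"))))
  expect_true(all(build_contingency(cls[0, ]) == 0L))

  # locus-level majority with ties to M0
  cls2 <- data.frame(
    locus_row = c(1L, 1L, 1L, 2L, 2L),
    locus_length = 40L,
    locus_n_mismatches = c(2L, 2L, 2L, 4L, 4L),
    verdict = c("M1", "M1", "M0", "M1", "M0"),
    stringsAsFactors = FALSE)
  tab2 <- build_contingency(cls2, locus_level = TRUE)
  expect_equal(as.vector(tab2), c(0L, 1L, 1L, 0L))
})

test_that("yates_chi2 matches the closed form and classical properties", {
  r1 <- yates_chi2(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(r1$chi2, 60 * (300 - 30)^2 / 30^4)
  expect_equal(r1$chi2, 5.4, tolerance = 1e-12)
  expect_equal(yates_chi2(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  r3 <- yates_chi2(matrix(c(0, 30, 30, 0), 2, byrow = TRUE))
  expect_equal(r3$chi2, 60 * (900 - 30)^2 / 30^4)
  expect_equal(r3$chi2, 56.06666667, tolerance = 1e-8)
  expect_error(yates_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")

  set.seed(17)
  for (i in 1:40) {
    tb <- matrix(sample(1:40, 4, replace = TRUE), 2)
    y <- yates_chi2(tb)
    ref <- suppressWarnings(chisq.test(tb, correct = TRUE))
    expect_equal(y$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(y$p_value, ref$p.value, tolerance = 1e-10)
    uncorr <- suppressWarnings(chisq.test(tb, correct = FALSE))
    expect_lte(y$chi2, unname(uncorr$statistic) + 1e-12)
    expect_equal(yates_chi2(t(tb))$chi2, y$chi2, tolerance = 1e-12)
    expect_equal(yates_chi2(tb[2:1, ])$chi2, y$chi2, tolerance = 1e-12)
    expect_equal(yates_chi2(tb[, 2:1])$chi2, y$chi2, tolerance = 1e-12)
  }
})

test_that("planted M0/M1 fractions are recovered from synthetic genomes", {
  sp <- synthetic_genome_spec(seed = 91, length = 9000, planted = list(
    planted_locus("AC", 45, n_mismatches = 3),
    planted_locus("AAG", 45, n_mismatches = 2),
    planted_locus("AT", 40, n_mismatches = 2),
    planted_locus("AGAT", 60, n_mismatches = 4)))
  sg <- generate_genome(sp)
  table <- detect_microsatellites(sg$genome)
  for (q in c(0, 1)) {
    snps <- generate_snps(sg, n_snps = 10, q = q, seed = 3)
    cl <- classify_m0_m1(map_snps_to_loci(snps, table, sg$genome))
    expect_equal(nrow(cl), 10L)
    expect_true(all(cl$verdict == if (q == 1) "M1" else "M0"))
  }
})
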