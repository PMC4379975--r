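test_that("motif canonicalization minimizes over rotations and strands", {
  expect_equal(standardize_motif(c("TG", "GAA", "A")), c("AC", "AAG", "A"))
  # idempotence and invariance under rotation / reverse complement
  set.seed(3)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    repeat {
      m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
      if (is_primitive_motif(m)) break
    }
    std <- standardize_motif(m)
    expect_equal(standardize_motif(std), std)
    rot <- sample(k, 1)
    rotated <- paste0(substr(m, rot, k), substr(m, 1, rot - 1))
    expect_equal(standardize_motif(rotated), std)
    expect_equal(standardize_motif(revcomp(m)), std)
  }
  expect_error(standardize_motif("ACAC"), "primitive")
  expect_error(standardize_motif("ACN"), "A,C,G,T")
})

test_that("locus_score implements the fixed-penalty rule", {
  p <- detection_params()
  expect_equal(locus_score(20, 1, p), 15L)
  expect_equal(locus_score(30, 3, p), 15L)
  expect_equal(locus_score(16, 0, p), 16L)
  expect_equal(locus_score(25, 2, detection_params(mismatch_penalty = 3)),
               19L)
  expect_error(locus_score(0, 0, p))
})

test_that("find_seeds reports maximal primitive perfect runs", {
  p <- detection_params()
  s1 <- find_seeds("ACACACAC", 2, p)
  expect_equal(s1, data.frame(start = 0L, end = 8L, motif = "AC"))
  expect_equal(nrow(find_seeds("ACACAC", 2, p)), 0L)   # 6 bp < 8 bp
  expect_equal(nrow(find_seeds("AAAAAAAA", 2, p)), 0L) # AA not primitive
  expect_equal(find_seeds("AAAAAAAA", 1, p),
               data.frame(start = 0L, end = 8L, motif = "A"))
  # N splits runs
  s2 <- find_seeds("ACACACACACNACACACACAC", 2, p)
  expect_equal(s2$start, c(0L, 11L))
  expect_equal(s2$end, c(10L, 21L))
})

test_that("extend_seed absorbs mismatches and trims to maximal score", {
  p <- detection_params()
  # mismatch in the middle: whole 20 bp tract, m = 1, mismatch offset 9
  s <- "ACACACACAGACACACACAC"
  seed <- find_seeds(s, 2, p)
  loc <- extend_seed(s, seed[which.max(seed$end - seed$start), ], p)
  expect_equal(loc$start, 0L)
  expect_equal(loc$end, 20L)
  expect_equal(loc$n_mismatches, 1L)
  expect_equal(loc$mismatch_positions[[1]], 9L)
  expect_equal(loc$score, 15L)

  # flanked by non-matching bases: candidate is the seed, perfect, but
  # scores below threshold -> NULL
  s2 <- "TTACACACACTT"
  seed2 <- find_seeds(s2, 2, p)
  expect_null(extend_seed(s2, seed2, p))
  # with a permissive threshold the tract is the seed alone
  p10 <- detection_params(min_score = 8)
  loc2 <- extend_seed(s2, seed2, p10)
  expect_equal(c(loc2$start, loc2$end, loc2$n_mismatches), c(2L, 10L, 0L))

  # N stops the extension
  s3 <- "ACACACACACACACACNACACAC"
  loc3 <- extend_seed(s3, find_seeds(s3, 2, p)[1, ], p)
  expect_equal(loc3$end, 16L)
})

test_that("detect_microsatellites matches the worked examples", {
  p <- detection_params()
  t1 <- detect_microsatellites(c(chr1 = "ACACACACACACACAC"), p)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$motif, "AC")
  expect_equal(t1$length, 16L)
  expect_equal(t1$n_mismatches, 0L)
  expect_equal(t1$score, 16L)

  # 21 bp with one internal mismatch scores 16
  s21 <- with_n_flanks(make_tract("AT", 21, offsets = 10L, bases = "C"))
  t2 <- detect_microsatellites(c(chr1 = s21), p)
  expect_equal(nrow(t2), 1L)
  expect_equal(t2$length, 21L)
  expect_equal(t2$n_mismatches, 1L)
  expect_equal(t2$score, 16L)
  expect_equal(t2$mismatch_positions[[1]], 10L)

  # a 19 bp tract with one mismatch cannot reach the threshold: under
  # these search conditions every reported locus under 20 bp is perfect
  s19 <- with_n_flanks(make_tract("AT", 19, offsets = 9L, bases = "C"))
  expect_equal(nrow(detect_microsatellites(c(chr1 = s19), p)), 0L)
})

test_that("every reported locus satisfies the length/mismatch bounds", {
  p <- detection_params()
  set.seed(101)
  seen_imp <- 0L
  for (i in 1:80) {
    tab <- detect_microsatellites(
      c(chr = random_ssr_sequence(100, 200, p_plant = 0.8)), p)
    if (nrow(tab) == 0L) next
    validate_locus_table(tab, p)
    expect_true(all(tab$length >= p$min_score))
    expect_true(all(tab$length[tab$n_mismatches == 1] >= 20))
    expect_true(all(tab$length[tab$n_mismatches == 2] >= 25))
    expect_true(all(tab$length[tab$n_mismatches == 3] >= 30))
    expect_true(all(tab$length[tab$n_mismatches > 3] >= 35))
    # tract ends are matching positions; no long mismatch runs
    for (j in seq_len(nrow(tab))) {
      off <- tab$mismatch_positions[[j]]
      expect_false(0L %in% off || (tab$length[j] - 1L) %in% off)
      if (length(off) > 1) {
        runs <- rle(diff(off) == 1L)
        expect_true(all(runs$lengths[runs$values] + 1L <=
                          p$max_consecutive_mm))
      }
      expect_true(is_primitive_motif(tab$motif[j]))
    }
    seen_imp <- seen_imp + sum(!tab$is_perfect)
  }
  expect_gt(seen_imp, 10L)  # the property was exercised on imperfect loci
})

test_that("detection is deterministic and monotone in the score threshold", {
  set.seed(202)
  for (i in 1:25) {
    sq <- c(chr = random_ssr_sequence(120, 200, p_plant = 0.8))
    a <- detect_microsatellites(sq)
    b <- detect_microsatellites(sq)
    expect_identical(as.data.frame(a), as.data.frame(b))
    relaxed <- detect_microsatellites(sq, detection_params(min_score = 10))
    key_strict <- paste(a$chrom, a$start, a$end, a$motif)
    key_relax <- paste(relaxed$chrom, relaxed$start, relaxed$end,
                       relaxed$motif)
    expect_true(all(key_strict %in% key_relax))
  }
})

test_that("the seeded detector agrees with brute-force enumeration", {
  p <- detection_params()
  set.seed(7)
  for (i in 1:60) {
    sq <- c(chr = random_ssr_sequence(60, 160))
    expect_equal(comparable_loci(detect_microsatellites(sq, p)),
                 oracle_detect(sq, p), ignore_attr = TRUE)
  }
  # also under the two alternate published parameter sets
  for (alt in list(detection_params(min_score = 15, mismatch_penalty = 3),
                   detection_params(min_score = 10, mismatch_penalty = 5))) {
    for (i in 1:15) {
      sq <- c(chr = random_ssr_sequence(60, 160, params = alt))
      expect_equal(comparable_loci(detect_microsatellites(sq, alt)),
                   oracle_detect(sq, alt), ignore_attr = TRUE)
    }
  }
})
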