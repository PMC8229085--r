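test_that("primer search finds planted sites and honours IUPAC semantics", {
  set.seed(11)
  tpl <- random_dna(300)
  primer <- substr(tpl, 101, 120)
  hits <- find_primer_sites(tpl, primer, max_mismatch = 0)
  plus <- hits[hits$strand == "+", ]
  expect_true(100 %in% plus$start)
  expect_equal(plus$mismatches[plus$start == 100], 0)

  # R matches G: degenerate primer hits a concrete subject with 0 mismatches
  hits2 <- find_primer_sites("CCCCAGAATTCCCC", "ARAATT", max_mismatch = 0)
  expect_equal(nrow(hits2[hits2$strand == "+", ]), 1)
  expect_equal(hits2$start[hits2$strand == "+"], 4)
  expect_equal(hits2$mismatches[hits2$strand == "+"], 0)
})

test_that("primer search equals the exhaustive sliding-window oracle", {
  set.seed(23)
  for (rep in 1:20) {
    seq <- random_dna(866)
    primer <- random_dna(15)
    got <- find_primer_sites(seq, primer, max_mismatch = 1)
    want <- oracle_primer_hits(seq, primer, 1)
    expect_equal(got$strand, as.character(want$strand))
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("amplicon extraction recovers the planted interval and supports pre-cut bypass", {
  set.seed(5)
  tpl <- make_template(c(252, 296, 562, 654), seed = 5)
  fwd <- substr(tpl, 1, 20)
  rev <- oracle_revcomp(substr(tpl, 847, 866))
  construct <- paste0(random_dna(100), tpl, random_dna(100))
  amp <- extract_amplicon(construct, fwd, rev, max_mismatch = 0, id = "s1")
  expect_equal(nchar(amp$sequence), 866)
  expect_equal(amp$interval, c(100L, 966L))
  expect_identical(amp$sequence, tpl)
  expect_false(amp$pre_cut)

  # bare amplicon with no primer hits passes through flagged pre-cut
  bare <- random_dna(866)
  expect_message(amp2 <- extract_amplicon(bare, "GGGGGGGGGGGG", "CCCCCCCCCCCC",
                                          max_mismatch = 0, id = "s2"),
                 "pre-cut")
  expect_true(amp2$pre_cut)
  expect_identical(amp2$sequence, bare)

  # an input of the wrong length with no primers is an extraction error
  expect_error(extract_amplicon(random_dna(500), "GGGGGGGGGGGG",
                                "CCCCCCCCCCCC", max_mismatch = 0),
               class = "coihap_extraction_error")
})

test_that("with several forward hits, the pair nearest the expected length wins", {
  set.seed(7)
  tpl <- make_template(c(252, 296, 654), seed = 8)
  fwd <- substr(tpl, 1, 20)
  rev <- oracle_revcomp(substr(tpl, 847, 866))
  # plant a second, spurious forward-primer copy well inside the construct
  construct <- paste0(random_dna(60), fwd, random_dna(40), tpl, random_dna(50))
  amp <- extract_amplicon(construct, fwd, rev, max_mismatch = 0,
                          expected_length = 866, tolerance = 200)
  expect_equal(nchar(amp$sequence), 866)
  expect_identical(amp$sequence, tpl)
  # enumerate all pairs: 866 must be the closest achievable product length
  fh <- find_primer_sites(construct, fwd, 0); fh <- fh[fh$strand == "+", ]
  rh <- find_primer_sites(construct, rev, 0); rh <- rh[rh$strand == "-", ]
  lens <- outer(rh$start + nchar(rev), fh$start, "-")
  expect_equal(min(abs(lens - 866)), 0)
})

test_that("digestion reproduces the diagnostic MED fragment patterns exactly", {
  q1 <- digest_sequence(make_template(c(252, 296, 562, 654), seed = 1))
  expect_equal(q1$fragments, c(44L, 92L, 212L, 252L, 266L))
  expect_equal(q1$cut_positions, c(252L, 296L, 562L, 654L))

  sard <- digest_sequence(make_template(c(252, 296, 562, 654, 672), seed = 2))
  expect_equal(sard$fragments, c(18L, 44L, 92L, 194L, 252L, 266L))

  q2 <- digest_sequence(make_template(c(252, 296, 654), seed = 3))
  expect_equal(q2$fragments, c(44L, 212L, 252L, 358L))

  # site-free template: a single uncut fragment
  free <- digest_sequence(make_template(integer(0), seed = 4))
  expect_equal(free$fragments, 866L)
  expect_equal(free$cut_positions, integer(0))
})

test_that("digestion handles literal examples and rejects ambiguity codes", {
  d <- digest_sequence("AAAAGAATTTCCCC")
  expect_equal(d$cut_positions, 5L)
  expect_equal(d$fragments, c(5L, 9L))

  err <- expect_error(digest_sequence("AAAANGAATTTCCC"),
                      class = "coihap_digest_error")
  expect_match(conditionMessage(err), "5")
})

test_that("digestion agrees with the exhaustive IUPAC-expansion oracle", {
  set.seed(31)
  for (rep in 1:200) {
    seq <- random_dna(200)
    got <- digest_sequence(seq)
    expect_identical(got$cut_positions, oracle_digest_cuts(seq))
    expect_equal(sum(got$fragments), 200L)
  }
})

test_that("overlapping recognition matches each contribute their own cut", {
  # ApoI sites cannot physically overlap (R and Y are disjoint), so use a
  # toy enzyme whose site can: AAA in AAAA matches at two offsets
  enz <- restriction_enzyme("ToyI", "AAA", 1)
  d <- digest_sequence("CCAAAACC", enz)
  expect_equal(d$cut_positions, c(3L, 4L))
  expect_equal(d$fragments, c(1L, 3L, 4L))
})

test_that("pattern library is self-consistent and classification matches Fig-style patterns", {
  lib <- med_pattern_library()
  for (p in lib) {
    expect_equal(sum(p$expected_fragments), 866)
    expect_equal(sort(diff(c(0L, p$cut_positions, 866L))), p$expected_fragments)
  }

  q2_digest <- digest_sequence(make_template(c(252, 296, 654), seed = 9))
  expect_equal(classify_pattern(q2_digest, lib)$label, "MEDQ2")

  # gel-visible mode: the 18-bp Sardinian piece is discarded from both sides
  sard <- digest_sequence(make_template(c(252, 296, 562, 654, 672), seed = 10))
  cl <- classify_pattern(sard, lib, mode = "gel_visible_fragments",
                         gel_min_visible = 25)
  expect_equal(cl$label, "MEDQ1-Sardinian")
  expect_equal(cl$distance_to_best, 0)
  # hand-recomputed visible multisets
  vis_digest <- sard$fragments[sard$fragments >= 25]
  vis_pattern <- lib$`MEDQ1-Sardinian`$expected_fragments[
    lib$`MEDQ1-Sardinian`$expected_fragments >= 25]
  expect_equal(vis_digest, vis_pattern)
  expect_equal(vis_digest, c(44L, 92L, 194L, 252L, 266L))

  # unknown pattern -> unclassified with nearest reported
  odd <- digest_sequence(make_template(c(100, 500), seed = 11))
  cl2 <- classify_pattern(odd, lib)
  expect_equal(cl2$label, "unclassified")
  expect_gt(cl2$distance_to_best, 0)

  expect_error(classify_pattern(q2_digest, structure(list(), class = "pattern_library")),
               class = "coihap_config_error")
})
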