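toy_alignment <- c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT", s4 = "AAAA")

test_that("haplotype collapsing groups identical sequences deterministically", {
  tab <- collapse_haplotypes(c(a = "AAA", b = "AAA", c = "AAT", d = "ATT"))
  expect_equal(tab$h, 3)
  expect_equal(tab$frequencies, c(2L, 1L, 1L))
  expect_equal(tab$members$H01, c("a", "b"))

  same <- collapse_haplotypes(c(x = "GGG", y = "GGG", z = "GGG", w = "GGG"))
  expect_equal(same$h, 1)
  expect_equal(same$frequencies, 4L)

  expect_error(collapse_haplotypes(c(a = "AA", b = "AAA")),
               class = "coihap_data_error")
})

test_that("complete deletion removes gapped/ambiguous columns from comparison", {
  # column 2 has a gap, column 4 an N: both excluded, so a and b collapse
  tab <- collapse_haplotypes(c(a = "A-CN", b = "AGCT", c = "AGAT"))
  expect_equal(tab$h, 2)
  expect_equal(tab$sites_used, 2)
})

test_that("haplotype diversity matches exact fractions and is label-invariant", {
  hd <- haplotype_diversity(c(2, 1, 1))
  expect_equal(unname(hd["Hd"]), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(hd["Hd"]), oracle_hd(c(2, 1, 1)), tolerance = 1e-15)

  # invariance under relabeling/reordering of haplotypes and specimens
  set.seed(2)
  f <- c(7, 5, 3, 2, 1, 1)
  expect_equal(haplotype_diversity(f), haplotype_diversity(sample(f)))

  expect_equal(unname(haplotype_diversity(c(4))["Hd"]), 0)
  expect_error(haplotype_diversity(c(1)), class = "coihap_data_error")
})

test_that("nucleotide diversity follows the pairwise-difference formula", {
  expect_equal(unname(nucleotide_diversity(c(a = "ACGTACGTAC",
                                             b = "ACGTACGTAC"))["pi"]), 0)
  two <- nucleotide_diversity(c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  expect_equal(unname(two["pi"]), 0.1, tolerance = 1e-12)

  # internal consistency: pi == theta_pi / sites_used under complete deletion
  pop <- simulate_preset_population("MEDQ1", seed = 17)
  st <- diversity_stats(pop_seqs(pop))
  expect_equal(st$pi, st$theta_pi / st$sites_used, tolerance = 1e-12)
})

test_that("Tajima's D matches the independently coded evaluation to 1e-12", {
  got <- tajimas_d(toy_alignment)
  expect_true(got$defined)
  expect_equal(got$S, 2L)
  expect_equal(got$value, oracle_tajima_d(toy_alignment), tolerance = 1e-12)

  set.seed(14)
  for (rep in 1:5) {
    pop <- simulate_preset_population("MEDQ1", seed = 100 + rep)
    seqs <- pop_seqs(pop)
    expect_equal(tajimas_d(seqs)$value, oracle_tajima_d(seqs),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D is undefined, not zero, on monomorphic samples", {
  mono <- c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT")
  d <- tajimas_d(mono)
  expect_false(d$defined)
  expect_true(is.na(d$value))
  expect_match(d$reason, "segregating")
})

test_that("Ewens allele-count distribution matches exact fractions and the CRP recurrence", {
  # |s(4,k)| = 6, 11, 6, 1 at theta = 1 -> denominators 24
  expect_equal(ewens_k_distribution(4, 1), c(6, 11, 6, 1) / 24,
               tolerance = 1e-12)

  for (n in c(2, 5, 10, 30)) for (theta in c(0.3, 1, 4.7)) {
    expect_equal(ewens_k_distribution(n, theta), oracle_ewens(n, theta),
                 tolerance = 1e-10)
  }
  # normalisation up to n = 200 at machine precision
  for (theta in c(0.5, 3.2, 20)) {
    expect_equal(sum(ewens_k_distribution(200, theta)), 1, tolerance = 1e-12)
  }
  expect_error(ewens_k_distribution(10, 0), class = "coihap_config_error")
})

test_that("Fu's Fs reproduces the exact small-sample value and flags degeneracy", {
  # n = 4, theta = 1, k_obs = 2: S' = (11+6+1)/24 = 18/24, Fs = ln 3.
  # An alignment with haplotype counts (3,1) at distance 2 has
  # theta_pi = 3*1*2 / C(4,2) = 1 exactly, realising this case end to end.
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AATT")
  fs4 <- fus_fs(aln)
  expect_equal(fs4$theta_pi, 1, tolerance = 1e-15)
  expect_equal(fs4$k_obs, 2)
  expect_equal(fs4$s_prime, 18 / 24, tolerance = 1e-12)
  expect_equal(fs4$value, log(3), tolerance = 1e-12)

  mono <- c(a = "ACGT", b = "ACGT")
  fs <- fus_fs(mono)
  expect_false(fs$defined)
  expect_true(is.na(fs$value))
})

test_that("Fu's Fs is negative on star-like expansions with many rare haplotypes", {
  neg <- 0
  for (s in 1:5) {
    pop <- simulate_preset_population("MEDQ1", seed = 300 + s)
    fs <- fus_fs(pop_seqs(pop))
    expect_true(fs$defined)
    expect_equal(fs$k_obs, 13)
    if (fs$value < 0) neg <- neg + 1
  }
  expect_equal(neg, 5)
})

test_that("diversity_stats bundles all statistics coherently", {
  pop <- simulate_preset_population("MEDQ2", seed = 8)
  st <- diversity_stats(pop_seqs(pop))
  expect_equal(st$n, 23)
  expect_equal(st$h, 3)
  expect_equal(st$Hd, oracle_hd(c(19, 3, 1)), tolerance = 1e-12)
  expect_lt(st$pi, 0.001)
  expect_equal(st$tajima_d, oracle_tajima_d(pop_seqs(pop)), tolerance = 1e-12)
})
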