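test_that("templates are deterministic given a seed and reject bad cut sets", {
  a <- make_template(c(100, 400), seed = 42)
  b <- make_template(c(100, 400), seed = 42)
  c <- make_template(c(100, 400), seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_equal(nchar(a), 866)

  expect_error(make_template(c(400, 100)), class = "coihap_generation_error")
  expect_error(make_template(c(100, 103)), class = "coihap_generation_error")
  expect_error(make_template(c(0, 100)), class = "coihap_generation_error")
})

test_that("derived templates stay close to their base and carry their own sites", {
  tpl1 <- make_template(c(252, 296, 562, 654), seed = 1)
  tpl2 <- make_template(c(252, 296, 654), seed = 2, base = tpl1,
                        divergence = 25)
  d <- sum(strsplit(tpl1, "")[[1]] != strsplit(tpl2, "")[[1]])
  expect_lt(d, 45) # ~25 substitutions plus site edits
  expect_gt(d, 10)
  expect_equal(digest_sequence(tpl2)$cut_positions, c(252L, 296L, 654L))
})

test_that("zero-mutation single-haplotype population is monomorphic", {
  tpl <- make_template(c(252, 296, 654), seed = 3)
  pop <- simulate_population(tpl, n_specimens = 6, n_haplotypes = 1,
                             frequencies = 6, mutations_per_haplotype = 0,
                             seed = 1)
  expect_true(all(pop$records$sequence == tpl))
  tab <- collapse_haplotypes(pop_seqs(pop))
  expect_equal(tab$h, 1)
  expect_equal(unname(haplotype_diversity(tab)["Hd"]), 0)
})

test_that("population Hd equals Nei's formula for the configured frequencies", {
  tpl <- make_template(c(252, 296, 654), seed = 4)
  pop <- simulate_population(tpl, n_specimens = 23, n_haplotypes = 3,
                             frequencies = c(19, 3, 1),
                             mutations_per_haplotype = 1, seed = 9)
  tab <- collapse_haplotypes(pop_seqs(pop))
  expect_equal(sort(tab$frequencies, decreasing = TRUE), c(19L, 3L, 1L))
  expect_equal(unname(haplotype_diversity(tab)["Hd"]),
               oracle_hd(c(19, 3, 1)), tolerance = 1e-12)
})

test_that("frequency search matches the exhaustive-enumeration oracle", {
  # brute-force oracle over all 3-part compositions of 23
  best <- NULL; best_obj <- Inf
  for (f1 in 1:21) for (f2 in 1:(23 - f1 - 1)) {
    f3 <- 23 - f1 - f2
    if (f3 < 1) next
    obj <- abs(oracle_hd(c(f1, f2, f3)) - 0.312)
    if (obj < best_obj) { best_obj <- obj; best <- sort(c(f1, f2, f3), decreasing = TRUE) }
  }
  got <- frequencies_for_target_hd(23, 3, 0.312)
  expect_equal(sort(got$frequencies, decreasing = TRUE), best)
  expect_equal(got$achieved_hd, oracle_hd(best), tolerance = 1e-12)

  # degenerate targets
  expect_equal(frequencies_for_target_hd(23, 1, 0)$frequencies, 23)
  even <- frequencies_for_target_hd(4, 4, 1.0)
  expect_equal(even$frequencies, c(1L, 1L, 1L, 1L))
  expect_equal(even$achieved_hd, 1.0)
  # infeasible target: nearest achievable returned, not an error
  infeasible <- frequencies_for_target_hd(10, 2, 0.99)
  expect_equal(sort(infeasible$frequencies, decreasing = TRUE), c(5L, 5L))
})

test_that("generated populations are reproducible and classify back to their template", {
  for (label in c("MEDQ1", "MEDQ2", "MEDQ1-Sardinian")) {
    p1 <- simulate_preset_population(label, seed = 21)
    p2 <- simulate_preset_population(label, seed = 21)
    expect_identical(p1$records, p2$records)
    cls <- classify_specimens(pop_seqs(p1))
    expect_true(all(cls$label == label))
  }
})

test_that("mutation budget larger than the mutable positions is an error", {
  tpl <- make_template(c(252, 296, 654), seed = 6)
  expect_error(simulate_population(tpl, 4, 2, frequencies = c(3, 1),
                                   mutations_per_haplotype = 900, seed = 1),
               class = "coihap_generation_error")
})

test_that("the MEDQ1 preset hits its diversity targets", {
  pop <- simulate_preset_population("MEDQ1", seed = 31)
  tab <- collapse_haplotypes(pop_seqs(pop))
  expect_equal(tab$h, 13)
  hd <- unname(haplotype_diversity(tab)["Hd"])
  expect_equal(hd, nei_hd(pop$frequencies), tolerance = 1e-12)
  expect_lt(abs(hd - 0.908), 0.01)
  pi <- unname(nucleotide_diversity(pop_seqs(pop))["pi"])
  expect_gt(pi, 0.003)
  expect_lt(pi, 0.005)
})
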