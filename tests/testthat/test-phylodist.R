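test_that("TN93 distance is zero on identity, symmetric, and matches the closed form", {
  set.seed(6)
  a <- random_dna(200)
  expect_equal(tn93_distance(a, a), 0)

  for (rep in 1:10) {
    x <- random_dna(300)
    # mutate ~5% of sites
    xv <- strsplit(x, "")[[1]]
    pos <- sample(300, 15)
    for (p in pos) xv[p] <- sample(setdiff(c("A", "C", "G", "T"), xv[p]), 1)
    y <- paste(xv, collapse = "")
    expect_equal(tn93_distance(x, y), tn93_distance(y, x), tolerance = 1e-15)
    expect_equal(tn93_distance(x, y), oracle_tn93(x, y), tolerance = 1e-10)
  }
})

test_that("TN93 matches the closed form on a fixture with planted substitution counts", {
  # 100 bp, 3 A<->G transitions, 2 C<->T transitions, 2 transversions
  set.seed(9)
  base <- strsplit(random_dna(100), "")[[1]]
  base[1:3] <- "A"; base[11:12] <- "C"; base[21:22] <- "A"
  other <- base
  other[1:3] <- "G"         # purine transitions
  other[11:12] <- "T"       # pyrimidine transitions
  other[21:22] <- "C"       # transversions
  a <- paste(base, collapse = ""); b <- paste(other, collapse = "")
  expect_equal(tn93_distance(a, b), oracle_tn93(a, b), tolerance = 1e-10)
  expect_gt(tn93_distance(a, b), 0.07 * 0.9)

  # saturated pairs are flagged NA, not returned as numbers
  sat <- tn93_distance(paste(rep("A", 30), collapse = ""),
                       paste(rep(c("C", "G", "T"), 10), collapse = ""))
  expect_true(is.na(sat))
  expect_true(isTRUE(attr(sat, "saturated")))
})

test_that("NJ recovers three-taxon branch lengths and additive splits", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  # closed three-point formulas: x = (dab + dac - dbc)/2 etc.
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens["a"]), 1)
  expect_equal(unname(lens["b"]), 2)
  expect_equal(unname(lens["c"]), 3)

  # additive 4x4 matrix from a known tree with split ab|cd
  # ((a:1,b:2):3,(c:1.5,d:2.5));
  D4 <- matrix(c(0, 3, 5.5, 6.5,
                 3, 0, 6.5, 7.5,
                 5.5, 6.5, 0, 4,
                 6.5, 7.5, 4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr4 <- nj_tree(D4)
  # the generating split is recovered: a,b form a cherry
  cherry <- ape::prop.part(tr4)
  parts <- lapply(cherry, function(p) sort(attr(cherry, "labels")[p]))
  expect_true(list(c("a", "b")) %in% parts || list(c("c", "d")) %in% parts)
  # path lengths reproduce the additive matrix
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr4))[letters[1:4], letters[1:4]]),
               unname(D4), tolerance = 1e-9)

  # degenerate all-zero matrix: star tree, label order preserved
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star <- nj_tree(Z)
  expect_equal(star$Nnode, 1L)
  expect_equal(star$tip.label, letters[1:4])
  expect_true(all(star$edge.length == 0))

  expect_error(nj_tree(matrix(0, 2, 2)), class = "coihap_data_error")
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), class = "coihap_data_error")
})

test_that("simulated haplogroups separate into connected clusters on the NJ tree", {
  sv <- simulate_survey(seed = 13)
  t1 <- collapse_haplotypes(pop_seqs(sv$MEDQ1))
  t2 <- collapse_haplotypes(pop_seqs(sv$MEDQ2))
  seqs <- c(setNames(t1$haplotypes$sequence, paste0("Q1_", t1$haplotypes$haplotype_id)),
            setNames(t2$haplotypes$sequence, paste0("Q2_", t2$haplotypes$haplotype_id)))
  tr <- nj_tree(tn93_matrix(seqs))
  # each haplogroup spans a connected subtree: some edge splits the tips
  # exactly into the Q1 set and the Q2 set
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  q1 <- sort(grep("^Q1_", labs, value = TRUE))
  found <- any(vapply(parts, function(p) {
    side <- sort(labs[p])
    identical(side, q1) || identical(sort(setdiff(labs, side)), q1)
  }, logical(1)))
  expect_true(found)
})

test_that("Newick output quotes awkward labels and round-trips", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(c("sp 1", "sp(2)", "sp3"),
                              c("sp 1", "sp(2)", "sp3")))
  tr <- nj_tree(D)
  nwk <- write_newick(tr)
  expect_match(nwk, "'sp 1'", fixed = TRUE)
  expect_match(nwk, "'sp(2)'", fixed = TRUE)
  back <- ape::read.tree(text = nwk)
  # ape keeps the protective quotes as part of the label; strip them to
  # compare the label content
  unq <- function(x) gsub("''", "'", sub("^'(.*)'$", "\\1", x))
  expect_setequal(unq(back$tip.label), c("sp 1", "sp(2)", "sp3"))

  set.seed(12)
  for (rep in 1:5) {
    tr <- ape::rtree(6)
    nwk <- write_newick(tr)
    back <- ape::read.tree(text = nwk)
    expect_setequal(back$tip.label, tr$tip.label)
    expect_equal(unname(as.matrix(ape::cophenetic.phylo(back))[tr$tip.label, tr$tip.label]),
                 unname(as.matrix(ape::cophenetic.phylo(tr))[tr$tip.label, tr$tip.label]),
                 tolerance = 1e-8)
  }

  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_true(file.exists(path))
})
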