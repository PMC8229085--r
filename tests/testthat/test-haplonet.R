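test_that("Hamming matrix matches a naive recount", {
  expect_equal(hamming_matrix(c(a = "TAA", b = "TAA"))[1, 2], 0L)
  expect_equal(hamming_matrix(c(a = "TAA", b = "ATA"))[1, 2], 2L)

  set.seed(4)
  haps <- setNames(replicate(13, random_dna(120)), paste0("H", 1:13))
  D <- hamming_matrix(haps)
  M <- do.call(rbind, strsplit(unname(haps), ""))
  expect_equal(unname(D), oracle_hamming(M))
  expect_true(isSymmetric(unname(D) * 1.0))
  expect_true(all(diag(D) == 0))

  expect_error(hamming_matrix(c(a = "AC", b = "ACA")),
               class = "coihap_data_error")
})

test_that("trivial networks: one node, and a single-step pair", {
  one <- median_joining(c(h1 = "ACGT"))
  expect_equal(nrow(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)

  two <- median_joining(c(h1 = "AAAA", h2 = "AAAT"))
  expect_equal(nrow(two$nodes), 2)
  expect_equal(two$edges$weight, 1L)
  expect_true(all(two$nodes$kind == "observed"))
})

test_that("the three-haplotype toy gains exactly one median and cost 3", {
  net <- median_joining(c(a = "TAA", b = "ATA", c = "AAT"))
  med <- net$nodes[net$nodes$kind == "median", ]
  expect_equal(nrow(med), 1)
  expect_equal(med$sequence, "AAA")
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  expect_equal(network_cost(net), 3)
  expect_equal(sum(net$nodes$size[net$nodes$kind == "observed"]), 3)
  expect_true(all(net$nodes$size[net$nodes$kind == "median"] == 0))
})

test_that("network cost equals the exhaustive Steiner optimum on small instances", {
  set.seed(42)
  tried <- 0
  while (tried < 25) {
    h <- sample(3:4, 1); s <- sample(3:5, 1)
    M <- matrix(sample(c("A", "T", "G"), h * s, replace = TRUE,
                       prob = c(.45, .45, .1)), h, s)
    if (anyDuplicated(apply(M, 1, paste, collapse = ""))) next
    tried <- tried + 1
    seqs <- setNames(apply(M, 1, paste, collapse = ""), paste0("h", 1:h))
    net <- median_joining(seqs, epsilon = 0)
    expect_equal(network_cost(net), oracle_steiner_cost(M),
                 info = paste(seqs, collapse = " "))
  }
})

test_that("network invariants hold on simulated star-like populations", {
  pop <- simulate_preset_population("MEDQ1", seed = 19)
  tab <- collapse_haplotypes(pop_seqs(pop))
  net <- median_joining(tab)
  # connected, positive weights, observed sizes sum to n, unique sequences
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  expect_true(all(net$edges$weight >= 1))
  expect_equal(sum(net$nodes$size[net$nodes$kind == "observed"]), 31)
  expect_false(anyDuplicated(net$nodes$sequence) > 0)
  # star-like: one node adjacent to at least half of the remaining nodes
  deg <- igraph::degree(g)
  expect_gte(max(deg), (nrow(net$nodes) - 1) / 2)
})

test_that("epsilon relaxation only ever adds edges", {
  set.seed(77)
  for (rep in 1:5) {
    pop <- simulate_preset_population("MEDQ1", seed = 400 + rep)
    tab <- collapse_haplotypes(pop_seqs(pop))
    haps <- setNames(tab$haplotypes$sequence, tab$haplotypes$haplotype_id)
    e0 <- median_joining(haps, epsilon = 0)
    e1 <- median_joining(haps, epsilon = 1)
    key <- function(net) {
      obs <- net$edges[net$edges$from %in% names(haps) &
                         net$edges$to %in% names(haps), ]
      paste(pmin(obs$from, obs$to), pmax(obs$from, obs$to))
    }
    expect_true(all(key(e0) %in% key(e1)))
  }
})

test_that("trait annotations change node metadata but never the topology", {
  pop <- simulate_preset_population("MEDQ1", seed = 23)
  tab <- collapse_haplotypes(pop_seqs(pop))
  traits <- data.frame(haplotype_id = tab$haplotypes$haplotype_id,
                       group = rep(c("Campania", "Molise", "Latium", "Marche"),
                                   length.out = tab$h),
                       count = tab$frequencies)
  plain <- median_joining(tab)
  annotated <- median_joining(tab, traits = traits)
  expect_identical(plain$nodes, annotated$nodes)
  expect_identical(plain$edges, annotated$edges)
  expect_false(is.null(annotated$traits))
})

test_that("networks round-trip through GraphML and the NEXUS network block", {
  pop <- simulate_preset_population("MEDQ2", seed = 3)
  tab <- collapse_haplotypes(pop_seqs(pop))
  traits <- data.frame(haplotype_id = tab$haplotypes$haplotype_id,
                       group = "Sicily", count = tab$frequencies)
  net <- median_joining(tab, traits = traits)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_equal(back$nodes[order(back$nodes$id), ],
               net$nodes[order(net$nodes$id), ], ignore_attr = TRUE)
  norm_edges <- function(e) {
    e2 <- data.frame(from = pmin(e$from, e$to), to = pmax(e$from, e$to),
                     weight = e$weight)
    e2[order(e2$from, e2$to), ]
  }
  expect_equal(norm_edges(back$edges), norm_edges(net$edges),
               ignore_attr = TRUE)

  nex <- withr::local_tempfile(fileext = ".nex")
  export_network(net, nex, "nexus")
  txt <- readLines(nex)
  expect_true(any(grepl("BEGIN TRAITS;", txt)))
  back2 <- import_network(nex, "nexus")
  expect_equal(norm_edges(back2$edges), norm_edges(net$edges),
               ignore_attr = TRUE)
  expect_equal(back2$nodes$size[order(back2$nodes$id)],
               net$nodes$size[order(net$nodes$id)])

  # no traits -> no Traits block
  net0 <- median_joining(tab)
  export_network(net0, nex, "nexus")
  expect_false(any(grepl("BEGIN TRAITS;", readLines(nex))))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edgelist")
  expect_equal(nrow(import_network(tsv, "edgelist")), nrow(net$edges))

  expect_error(export_network(net, tsv, "dot"), class = "coihap_config_error")
})
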