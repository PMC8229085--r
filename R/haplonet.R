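# Median-joining haplotype networks, built from first principles:
# minimum-spanning network over observed haplotypes, augmented with median
# (Steiner) vectors that reduce the total connection cost, iterated to a
# fixpoint, then pruned of obsolete medians.

#' Hamming distance matrix between haplotype sequences
#'
#' Counts differing columns between every pair of equal-length sequences.
#'
#' @param haplotypes Named character vector of equal-length sequences.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
hamming_matrix <- function(haplotypes) {
  haplotypes <- as_seq_vector(haplotypes)
  mat <- seq_matrix(haplotypes)
  n <- nrow(mat)
  D <- matrix(0L, n, n, dimnames = list(names(haplotypes), names(haplotypes)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- sum(mat[i, ] != mat[j, ])
  }
  D
}

hamming_rows <- function(M) {
  n <- nrow(M)
  D <- matrix(0L, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(M[i, ] != M[j, ])
  D
}

# Prim MST on a full distance matrix; returns edge list (i, j, w) and cost.
mst_edges <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(list(edges = matrix(numeric(0), 0, 3), cost = 0))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best_d <- D[1, ]; best_from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_d[cand])]
    edges[k, ] <- c(best_from[v], v, best_d[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best_d
    best_from[upd] <- v
    best_d[upd] <- D[v, upd]
  }
  list(edges = edges, cost = sum(edges[, 3]))
}

mst_cost <- function(D) mst_edges(D)$cost

# Bottleneck (minimax-edge) distances between all node pairs, via the MST.
bottleneck_matrix <- function(D) {
  n <- nrow(D)
  B <- matrix(0, n, n)
  if (n == 1L) return(B)
  e <- mst_edges(D)$edges
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1]; j <- e[k, 2]; w <- e[k, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  for (src in seq_len(n)) {
    # DFS from src over the tree, tracking the max edge weight en route
    stack <- list(c(src, -1, 0))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- top[1]; parent <- top[2]; mx <- top[3]
      if (v != src) B[src, v] <- mx
      nb <- adj[[v]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        if (nb[r, 1] != parent)
          stack[[length(stack) + 1]] <- c(nb[r, 1], v, max(mx, nb[r, 2]))
      }
    }
  }
  B
}

# Minimum-spanning network with relaxation epsilon: all edges whose weight
# is within epsilon of the bottleneck distance between their endpoints
# (epsilon = 0 gives exactly the union of all minimum spanning trees).
msn_edges <- function(D, epsilon = 0L) {
  n <- nrow(D)
  if (n < 2L) return(matrix(numeric(0), 0, 3))
  B <- bottleneck_matrix(D)
  out <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] <= B[i, j] + epsilon)
      out <- rbind(out, c(i, j, D[i, j]))
  out
}

# Majority-state median of three rows; where all three states differ the
# candidate keeps the state of the first row (processing order).
triple_median <- function(M, idx) {
  idx <- sort(idx)
  a <- M[idx[1], ]; b <- M[idx[2], ]; c <- M[idx[3], ]
  out <- a
  ab <- a == b; acc <- a == c; bc <- b == c
  out[bc & !ab] <- b[bc & !ab]
  out
}

#' Build a median-joining haplotype network
#'
#' Implements the median-joining construction: (1) restrict sequences to
#' their segregating columns; (2) connect observed haplotypes by the
#' minimum-spanning network (union of all minimum spanning trees, with
#' additional links admitted up to `epsilon` mutations beyond the
#' bottleneck threshold); (3) for node triples connected in the network,
#' compute per-column majority (median) vectors and add, one at a time, the
#' median that most reduces the total connection cost (the weight of a
#' minimum spanning tree over the augmented node set); when no single median
#' reduces the cost, pairs of candidate medians are tried, since two interior
#' vectors can be jointly cost-reducing where neither helps alone; (4)
#' iterate to a fixpoint; (5) iteratively delete obsolete median nodes (degree <= 2
#' nodes lying on no shortest connection between observed haplotypes).
#'
#' Determinism: nodes are processed in first-occurrence order, candidate
#' medians in lexicographic sequence order, and cost ties break toward the
#' lexicographically smallest sequence. Where the three states of a triple
#' all differ at a column, the median keeps the state of the first node in
#' processing order.
#'
#' @param haplotypes Named character vector of haplotype sequences, or a
#'   `haplotype_table` from [collapse_haplotypes()].
#' @param frequencies Haplotype counts (taken from the table when one is
#'   given; default 1 each).
#' @param epsilon Non-negative integer link relaxation (default 0).
#' @param traits Optional data.frame `(haplotype_id, group, count)` whose
#'   per-group counts annotate the observed nodes.
#' @return An object of class `haplotype_network`: list with `nodes`
#'   (data.frame `id`, `sequence` over segregating columns, `kind`
#'   observed/median, `size`), `edges` (data.frame `from`, `to`, `weight`),
#'   `epsilon`, `seg_columns`, `traits`.
#' @examples
#' net <- median_joining(c(a = "TAA", b = "ATA", c = "AAT"))
#' net$nodes # three observed nodes plus the median "AAA"
#' @export
median_joining <- function(haplotypes, frequencies = NULL, epsilon = 0L,
                           traits = NULL) {
  if (inherits(haplotypes, "haplotype_table")) {
    tab <- haplotypes
    haplotypes <- stats::setNames(tab$haplotypes$sequence,
                                  tab$haplotypes$haplotype_id)
    frequencies <- frequencies %||% tab$frequencies
  }
  haplotypes <- as_seq_vector(haplotypes)
  if (anyDuplicated(haplotypes))
    coihap_error("coihap_data_error", "haplotype sequences must be unique")
  epsilon <- as.integer(epsilon)
  if (epsilon < 0L)
    coihap_error("coihap_config_error", "epsilon must be a non-negative integer")
  frequencies <- as.integer(frequencies %||% rep(1L, length(haplotypes)))
  n_obs <- length(haplotypes)
  full <- seq_matrix(haplotypes)
  used <- used_columns(full)
  seg <- used[apply(full[, used, drop = FALSE], 2,
                    function(col) length(unique(col)) > 1)]
  M <- full[, seg, drop = FALSE]
  node_seq <- apply(M, 1, paste, collapse = "")
  if (n_obs == 1L) {
    nodes <- data.frame(id = names(haplotypes), sequence = node_seq,
                        kind = "observed", size = frequencies,
                        stringsAsFactors = FALSE)
    return(new_haplonet(nodes,
                        data.frame(from = character(0), to = character(0),
                                   weight = integer(0)),
                        epsilon, seg, traits))
  }
  kind <- rep("observed", n_obs)
  n_median <- 0L
  # ---- median augmentation to fixpoint ----
  repeat {
    D <- hamming_rows(M)
    base_cost <- mst_cost(D)
    E <- msn_edges(D, epsilon)
    # neighbour lists
    nn <- nrow(M)
    adj <- vector("list", nn)
    if (!is.null(E)) for (k in seq_len(nrow(E))) {
      i <- E[k, 1]; j <- E[k, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    # triples with at least two links through a common node
    cand_seqs <- character(0)
    for (u in seq_len(nn)) {
      nb <- adj[[u]]
      if (length(nb) < 2L) next
      for (pair in utils::combn(sort(nb), 2, simplify = FALSE)) {
        med <- triple_median(M, c(u, pair))
        cand_seqs <- c(cand_seqs, paste(med, collapse = ""))
      }
    }
    cand_seqs <- sort(unique(setdiff(cand_seqs,
                                     apply(M, 1, paste, collapse = ""))))
    if (length(cand_seqs) == 0L) break
    best_gain <- 0; best_add <- NULL
    for (cs in cand_seqs) {
      row <- strsplit(cs, "", fixed = TRUE)[[1]]
      d_new <- colSums(t(M) != row)
      D2 <- rbind(cbind(D, d_new), c(d_new, 0))
      gain <- base_cost - mst_cost(D2)
      if (gain > best_gain) { best_gain <- gain; best_add <- list(row) }
    }
    if (is.null(best_add) && nrow(M) <= 25L && length(cand_seqs) <= 60L) {
      # Two medians can be jointly cost-reducing where neither helps alone
      # (a pair of interior vectors bridging two distant pairs). Partners
      # for each candidate are the other candidates plus the second-level
      # medians of triples that involve the candidate itself.
      node_keys <- apply(M, 1, paste, collapse = "")
      rows <- lapply(cand_seqs, function(cs) strsplit(cs, "", fixed = TRUE)[[1]])
      for (a in seq_along(rows)) {
        Ma <- rbind(M, rows[[a]])
        ai <- nrow(Ma)
        lvl2 <- character(0)
        for (pair in utils::combn(nrow(M), 2, simplify = FALSE))
          lvl2 <- c(lvl2, paste(triple_median(Ma, c(pair, ai)), collapse = ""))
        partners <- sort(unique(setdiff(c(cand_seqs[-a], lvl2),
                                        c(node_keys, cand_seqs[a]))))
        for (ps in partners) {
          M2 <- rbind(Ma, strsplit(ps, "", fixed = TRUE)[[1]])
          gain <- base_cost - mst_cost(hamming_rows(M2))
          if (gain > best_gain) {
            best_gain <- gain
            best_add <- list(rows[[a]], strsplit(ps, "", fixed = TRUE)[[1]])
          }
        }
      }
    }
    if (is.null(best_add)) break
    for (row in best_add) M <- rbind(M, row)
    kind <- c(kind, rep("median", length(best_add)))
    n_median <- n_median + length(best_add)
    if (n_median > 10L * n_obs + 50L) break # safety bound; cost is strictly decreasing
  }
  ids <- c(names(haplotypes),
           if (n_median > 0L) sprintf("MV%02d", seq_len(n_median)))
  rownames(M) <- ids
  sizes <- c(frequencies, rep(0L, n_median))
  # ---- prune obsolete medians ----
  repeat {
    D <- hamming_rows(M)
    E <- msn_edges(D, epsilon)
    deg <- tabulate(c(E[, 1], E[, 2]), nbins = nrow(M))
    med_idx <- which(kind == "median")
    drop <- NA_integer_
    for (m in med_idx) {
      if (deg[m] > 2L) next
      if (deg[m] <= 1L) { drop <- m; break }
      if (!on_minimal_path(m, E, D, which(kind == "observed"))) {
        drop <- m; break
      }
    }
    if (is.na(drop)) break
    M <- M[-drop, , drop = FALSE]
    kind <- kind[-drop]; ids <- ids[-drop]; sizes <- sizes[-drop]
  }
  D <- hamming_rows(M)
  E <- msn_edges(D, epsilon)
  edges <- if (is.null(E) || nrow(E) == 0L)
    data.frame(from = character(0), to = character(0), weight = integer(0))
  else
    data.frame(from = ids[E[, 1]], to = ids[E[, 2]],
               weight = as.integer(E[, 3]), stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, sequence = apply(M, 1, paste, collapse = ""),
                      kind = kind, size = sizes, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  new_haplonet(nodes, edges, epsilon, seg, traits)
}

# Does removing node m change any shortest-path distance between observed
# nodes (or disconnect them)?
on_minimal_path <- function(m, E, D, observed) {
  g_full <- igraph::graph_from_data_frame(
    data.frame(from = as.character(E[, 1]), to = as.character(E[, 2]),
               weight = E[, 3]),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nrow(D)))))
  g_red <- igraph::delete_vertices(g_full, as.character(m))
  obs <- as.character(observed)
  d_full <- igraph::distances(g_full, v = obs, to = obs)
  d_red <- igraph::distances(g_red, v = obs, to = obs)
  !isTRUE(all.equal(d_full, d_red))
}

new_haplonet <- function(nodes, edges, epsilon, seg_columns, traits) {
  if (!is.null(traits)) {
    need <- c("haplotype_id", "group", "count")
    if (!all(need %in% names(traits)))
      coihap_error("coihap_config_error",
                   "traits must have columns haplotype_id, group, count")
    traits <- traits[traits$haplotype_id %in% nodes$id, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon,
                 seg_columns = seg_columns, traits = traits),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  n_obs <- sum(x$nodes$kind == "observed")
  n_med <- sum(x$nodes$kind == "median")
  cat(sprintf("Median-joining network: %d observed + %d median nodes, %d edges (epsilon = %d, %d segregating columns)\n",
              n_obs, n_med, nrow(x$edges), x$epsilon, length(x$seg_columns)))
  cat(sprintf("  total edge weight: %d\n", sum(x$edges$weight)))
  invisible(x)
}

#' Total connection cost of a network
#'
#' Weight of a minimum spanning tree over all network nodes in the Hamming
#' metric of their (segregating-column) sequences -- the quantity the
#' median-joining augmentation minimises.
#'
#' @param network A `haplotype_network`.
#' @return Numeric cost.
#' @export
network_cost <- function(network) {
  M <- do.call(rbind, strsplit(network$nodes$sequence, "", fixed = TRUE))
  if (is.null(M) || nrow(M) < 2L) return(0)
  mst_cost(hamming_rows(M))
}

#' Convert a haplotype network to an igraph object
#'
#' @param network A `haplotype_network`.
#' @return An `igraph` graph with node attributes `sequence`, `kind`,
#'   `size` and edge attribute `weight`.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Plot a haplotype network
#'
#' Simple igraph rendering: observed nodes sized by frequency, median nodes
#' drawn as small filled squares.
#'
#' @param x A `haplotype_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.haplotype_network <- function(x, ...) {
  g <- as_igraph(x)
  obs <- igraph::V(g)$kind == "observed"
  igraph::plot.igraph(
    g,
    vertex.size = ifelse(obs, 8 + 4 * sqrt(pmax(igraph::V(g)$size, 1)), 3),
    vertex.shape = ifelse(obs, "circle", "square"),
    vertex.color = ifelse(obs, "steelblue", "grey30"),
    vertex.label = ifelse(obs, igraph::V(g)$name, NA),
    edge.label = igraph::E(g)$weight, ...)
  invisible(x)
}

#' Edge-cut grouping of a network
#'
#' Convenience partition of the nodes into connected components after
#' removing edges heavier than `threshold` mutations. This is an explicit
#' computational grouping; it is not an inference of "main haplotype
#' groups", which in published figures are typically hand-drawn
#' annotations.
#'
#' @param network A `haplotype_network`.
#' @param threshold Maximum edge weight kept (default 1).
#' @return Named integer vector of component memberships.
#' @export
edge_cut_groups <- function(network, threshold = 1L) {
  keep <- network$edges[network$edges$weight <= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(keep, directed = FALSE,
                                     vertices = network$nodes)
  igraph::components(g)$membership
}
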