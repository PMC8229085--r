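# Distance-based phylogenetic summaries: TN93 pairwise distances and
# neighbor-joining trees with Newick output. These are cluster sanity
# checks, not a substitute for full likelihood tree inference (which is a
# deliberate non-goal of this package): no gamma rate variation, no
# bootstrap.

pair_to_dnabin <- function(a, b) {
  m <- rbind(strsplit(tolower(a), "", fixed = TRUE)[[1]],
             strsplit(tolower(b), "", fixed = TRUE)[[1]])
  rownames(m) <- c("a", "b")
  ape::as.DNAbin(m)
}

#' TN93 distance between two sequences
#'
#' Tamura-Nei (1993) closed-form distance with empirical base frequencies
#' and separate purine (A<->G) and pyrimidine (C<->T) transition classes.
#' Frequencies are estimated from the pooled pair; columns containing a gap
#' or ambiguity code in either sequence are excluded. Saturated pairs (a
#' logarithm argument <= 0) are reported as `NA` with attribute
#' `saturated = TRUE` rather than as an arbitrary large number.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings.
#' @return Non-negative distance (substitutions per site), or flagged `NA`.
#' @export
tn93_distance <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    coihap_error("coihap_data_error", "sequences must have equal length")
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  ok <- a %in% VALID_BASES & b %in% VALID_BASES
  if (!any(ok))
    coihap_error("coihap_data_error", "no usable column in the pair")
  if (all(a[ok] == b[ok])) return(0)
  d <- suppressWarnings(
    ape::dist.dna(pair_to_dnabin(paste(a[ok], collapse = ""),
                                 paste(b[ok], collapse = "")),
                  model = "TN93", pairwise.deletion = FALSE))
  d <- as.numeric(d)
  if (!is.finite(d)) {
    out <- NA_real_
    attr(out, "saturated") <- TRUE
    return(out)
  }
  d
}

#' TN93 distance matrix
#'
#' Pairwise [tn93_distance()] over a set of sequences (frequencies pooled
#' per pair). Saturated pairs are `NA` and reported via a warning.
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return Symmetric numeric matrix with zero diagonal and sequence names
#'   as dimnames.
#' @export
tn93_matrix <- function(seqs) {
  seqs <- as_seq_vector(seqs)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  sat <- 0L
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- tn93_distance(seqs[[i]], seqs[[j]])
    if (is.na(d)) sat <- sat + 1L
    D[i, j] <- D[j, i] <- d
  }
  if (sat > 0L)
    warning(sprintf("%d saturated pair(s) reported as NA", sat), call. = FALSE)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]), returned as an unrooted
#' `phylo` tree. Negative branch lengths, an occasional artefact of NJ on
#' non-additive matrices, are clamped to zero with a message. A matrix of
#' all zeros yields a star tree with zero branch lengths, tips in label
#' order.
#'
#' @param d Symmetric numeric matrix (>= 3 labels, zero diagonal).
#' @return An [ape::phylo] object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L)
    coihap_error("coihap_data_error", "neighbor joining needs >= 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (any(is.na(d)))
    coihap_error("coihap_data_error",
                 "distance matrix contains NA (saturated pairs); remove or impute them")
  if (max(abs(d - t(d))) > 1e-12)
    coihap_error("coihap_data_error", "distance matrix must be symmetric")
  if (all(d == 0)) {
    n <- nrow(d)
    tr <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
               edge.length = rep(0, n),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("nj_tree: clamped %d negative branch length(s) to 0", sum(neg)))
    tr$edge.length[neg] <- 0
  }
  tr
}

newick_quote <- function(x) {
  if (grepl("[][():;,'\" \t]", x))
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  else x
}

#' Serialise a tree to Newick
#'
#' Standard Newick with branch lengths; labels containing Newick
#' metacharacters (parentheses, commas, colons, semicolons, quotes or
#' whitespace) are single-quoted per the format rules, so the output
#' round-trips through a standard parser.
#'
#' @param tree An [ape::phylo] object.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(x) formatC(x, format = "g", digits = 10)
  rec <- function(node) {
    if (node <= n_tip) return(newick_quote(tree$tip.label[node]))
    kids <- children[[as.character(node)]]
    parts <- vapply(kids, function(e) {
      child <- tree$edge[e, 2]
      len <- if (is.null(tree$edge.length)) NULL else tree$edge.length[e]
      paste0(rec(child), if (!is.null(len)) paste0(":", fmt_len(len)))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  out <- paste0(rec(root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
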