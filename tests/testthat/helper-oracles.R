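# Independent oracle implementations used across the suite. These are
# deliberately written with different algorithms/data structures than the
# package internals so that agreement is informative.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Exhaustive per-offset IUPAC scan: all 0-based plus-strand starts where the
# pattern matches the sequence with <= max_mm mismatches.
oracle_scan <- function(sequence, pattern, max_mm = 0L) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(p); L <- length(s)
  if (L < m) return(integer(0))
  hits <- integer(0)
  for (off in 0:(L - m)) {
    mm <- 0L
    for (k in seq_len(m))
      if (!(s[off + k] %in% IUPAC_ORACLE[[p[k]]])) mm <- mm + 1L
    if (mm <= max_mm) hits <- c(hits, off)
  }
  hits
}

# Cut prefix-lengths of a digestion, via the exhaustive scan.
oracle_digest_cuts <- function(sequence, recognition = "RAATTY",
                               cut_offset = 1L) {
  cuts <- oracle_scan(sequence, recognition, 0L) + cut_offset
  sort(unique(cuts[cuts > 0 & cuts < nchar(sequence)]))
}

# Both-strand primer scan as (strand, start0, mismatches) rows.
oracle_primer_hits <- function(sequence, primer, max_mm) {
  plus <- oracle_scan(sequence, primer, max_mm)
  minus <- oracle_scan(sequence, oracle_revcomp(primer), max_mm)
  mm_at <- function(pat, off) {
    s <- strsplit(sequence, "", fixed = TRUE)[[1]]
    p <- strsplit(pat, "", fixed = TRUE)[[1]]
    sum(!mapply(function(pc, sc) sc %in% IUPAC_ORACLE[[pc]],
                p, s[(off + 1):(off + length(p))]))
  }
  out <- rbind(
    if (length(plus)) data.frame(strand = "+", start = plus,
                                 mismatches = sapply(plus, function(o) mm_at(primer, o))),
    if (length(minus)) data.frame(strand = "-", start = minus,
                                  mismatches = sapply(minus, function(o) mm_at(oracle_revcomp(primer), o))))
  if (is.null(out)) return(data.frame(strand = character(0), start = integer(0),
                                      mismatches = integer(0)))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Nei's haplotype diversity, written as plain fractions.
oracle_hd <- function(freq) {
  n <- sum(freq)
  (n / (n - 1)) * (1 - sum(freq^2) / n^2)
}

# Tajima's D evaluated directly from the alignment with naive double loops.
oracle_tajima_d <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) k <- k + sum(m[i, ] != m[j, ])
  k <- k / (n * (n - 1) / 2)
  ii <- 1:(n - 1)
  a1 <- sum(1 / ii); a2 <- sum(1 / ii^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Ewens allele-count distribution via the sequential (Chinese-restaurant)
# recurrence -- an independent route that never touches Stirling numbers:
# P_{n+1}(k) = theta/(theta+n) P_n(k-1) + n/(theta+n) P_n(k).
oracle_ewens <- function(n, theta) {
  p <- 1 # n = 1: K = 1 surely
  if (n == 1) return(p)
  for (m in 1:(n - 1)) {
    p_new <- numeric(m + 1)
    p_new[2:(m + 1)] <- p_new[2:(m + 1)] + theta / (theta + m) * p
    p_new[1:m] <- p_new[1:m] + m / (theta + m) * p
    p <- p_new
  }
  p
}

# TN93 closed form with pooled-pair base frequencies.
oracle_tn93 <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  L <- length(av)
  all_bases <- c(av, bv)
  g <- sapply(c("A", "C", "G", "T"), function(x) mean(all_bases == x))
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  is_ts1 <- (av == "A" & bv == "G") | (av == "G" & bv == "A")
  is_ts2 <- (av == "C" & bv == "T") | (av == "T" & bv == "C")
  diff <- av != bv
  P1 <- mean(is_ts1); P2 <- mean(is_ts2); Q <- mean(diff & !is_ts1 & !is_ts2)
  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["T"] * g["C"] / gY
  k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["T"] * g["C"] * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  unname(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

# --- exhaustive Steiner search over Hamming space -------------------------
oracle_kruskal_cost <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  ed <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) ed <- rbind(ed, c(i, j, D[i, j]))
  ed <- ed[order(ed[, 3]), , drop = FALSE]
  parent <- 1:n
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  cost <- 0; cnt <- 0
  for (k in seq_len(nrow(ed))) {
    a <- find(ed[k, 1]); b <- find(ed[k, 2])
    if (a != b) {
      parent[a] <- b
      cost <- cost + ed[k, 3]
      cnt <- cnt + 1
      if (cnt == n - 1) break
    }
  }
  cost
}

oracle_hamming <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(M[i, ] != M[j, ])
  D
}

# Minimum Steiner-tree cost over terminals M (character matrix), allowing
# up to nrow(M) - 2 added points drawn from the per-column observed states.
oracle_steiner_cost <- function(M) {
  h <- nrow(M)
  states <- lapply(seq_len(ncol(M)), function(c) unique(M[, c]))
  cand <- as.matrix(expand.grid(states, stringsAsFactors = FALSE))
  tkey <- apply(M, 1, paste, collapse = "")
  cand <- cand[!apply(cand, 1, paste, collapse = "") %in% tkey, , drop = FALSE]
  best <- oracle_kruskal_cost(oracle_hamming(M))
  maxadd <- max(0, h - 2)
  if (nrow(cand) > 0 && maxadd > 0) for (sz in 1:maxadd) {
    for (comb in utils::combn(seq_len(nrow(cand)), sz, simplify = FALSE)) {
      cost <- oracle_kruskal_cost(oracle_hamming(rbind(M, cand[comb, , drop = FALSE])))
      if (cost < best) best <- cost
    }
  }
  best
}

pop_seqs <- function(pop) stats::setNames(pop$records$sequence,
                                          pop$records$specimen_id)
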