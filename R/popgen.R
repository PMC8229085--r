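# Population-genetics statistics computed from first principles on aligned
# haplotype sequences: haplotype collapsing, Nei's haplotype diversity,
# nucleotide diversity per site, segregating sites, Tajima's D and Fu's Fs
# (through the Ewens sampling formula).

VALID_BASES <- c("A", "C", "G", "T")

# Column handling. "complete_deletion" (the default, mirroring the common
# DnaSP behaviour) excludes any column containing a gap or ambiguity code
# from every statistic; "pairwise_deletion" drops unusable columns per
# sequence pair.
check_policy <- function(policy) {
  match.arg(policy, c("complete_deletion", "pairwise_deletion"))
}

used_columns <- function(mat) {
  which(apply(mat, 2, function(col) all(col %in% VALID_BASES)))
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical at all used columns share a haplotype. Under the
#' default `complete_deletion` policy the used columns are those free of
#' gaps and ambiguity codes across the whole alignment. Haplotypes are
#' numbered by first occurrence, which makes the numbering deterministic
#' for a fixed input order.
#'
#' @param seqs Named character vector of equal-length sequences (or a
#'   specimen data.frame with `specimen_id` and `sequence`).
#' @param policy Column-handling policy (haplotype comparison always uses
#'   the complete-deletion column set; the argument is kept for interface
#'   symmetry with the diversity estimators).
#' @return An object of class `haplotype_table`: list with `haplotypes`
#'   (data.frame `haplotype_id`, `sequence`, `count`), `members` (named
#'   list of specimen ids), `n`, `h`, `frequencies`, `sites_used` and
#'   `used_cols`.
#' @export
collapse_haplotypes <- function(seqs, policy = "complete_deletion") {
  check_policy(policy)
  seqs <- as_seq_vector(seqs)
  mat <- seq_matrix(seqs)
  used <- used_columns(mat)
  if (length(used) == 0L)
    coihap_error("coihap_data_error",
                 "no usable columns: every column has a gap or ambiguity code")
  key <- apply(mat[, used, drop = FALSE], 1, paste, collapse = "")
  uniq <- unique(key)
  idx <- match(key, uniq)
  h <- length(uniq)
  hap_ids <- sprintf("H%02d", seq_len(h))
  first_member <- match(uniq, key)
  haplotypes <- data.frame(
    haplotype_id = hap_ids,
    sequence = unname(seqs[first_member]),
    count = as.integer(tabulate(idx, h)),
    stringsAsFactors = FALSE)
  members <- split(names(seqs), hap_ids[idx])
  members <- members[hap_ids]
  structure(list(haplotypes = haplotypes, members = members,
                 n = length(seqs), h = h,
                 frequencies = haplotypes$count,
                 sites_used = length(used), used_cols = used,
                 assignment = stats::setNames(hap_ids[idx], names(seqs))),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table: n = %d sequences, h = %d haplotypes (%d sites used)\n",
              x$n, x$h, x$sites_used))
  print(head(data.frame(x$haplotypes[, c("haplotype_id", "count")],
                        members = vapply(x$members, function(m)
                          paste(head(m, 3), collapse = ","), character(1))),
             10))
  if (x$h > 10) cat("  ...\n")
  invisible(x)
}

#' Haplotype diversity with sampling standard deviation
#'
#' Nei's unbiased estimator `Hd = n/(n-1) * (1 - sum p_i^2)` and the
#' square root of Nei's sampling variance
#' `V = 2/(n(n-1)) * (2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2)`.
#'
#' @param x A `haplotype_table` or a vector of haplotype counts.
#' @return Named numeric vector `c(Hd =, Hd_sd =)`.
#' @export
haplotype_diversity <- function(x) {
  f <- if (inherits(x, "haplotype_table")) x$frequencies else as.numeric(x)
  n <- sum(f)
  if (n < 2)
    coihap_error("coihap_data_error",
                 "haplotype diversity is undefined for n < 2")
  p <- f / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(Hd = hd, Hd_sd = sqrt(max(v, 0)))
}

# Pairwise-difference machinery. Works at the haplotype level (distances
# between unique sequences weighted by their frequencies) so that large
# samples stay cheap.
pairwise_diff_stats <- function(seqs, policy) {
  policy <- check_policy(policy)
  seqs <- as_seq_vector(seqs)
  n <- length(seqs)
  if (n < 2)
    coihap_error("coihap_data_error", "need at least 2 sequences")
  mat <- seq_matrix(seqs)
  tab <- collapse_haplotypes(seqs)
  reps <- seq_matrix(stats::setNames(tab$haplotypes$sequence,
                                     tab$haplotypes$haplotype_id))
  f <- tab$frequencies
  npairs <- n * (n - 1) / 2
  if (policy == "complete_deletion") {
    used <- tab$used_cols
    sub <- reps[, used, drop = FALSE]
    L <- length(used)
    total_diff <- 0
    total_per_site <- 0
    h <- nrow(sub)
    if (h > 1) for (a in 1:(h - 1)) for (b in (a + 1):h) {
      d <- sum(sub[a, ] != sub[b, ])
      total_diff <- total_diff + f[a] * f[b] * d
      total_per_site <- total_per_site + f[a] * f[b] * d / L
    }
    k_hat <- total_diff / npairs
    pi <- total_per_site / npairs
    seg <- sum(apply(sub, 2, function(col) length(unique(col)) > 1))
  } else {
    h <- nrow(reps)
    total_diff <- 0; total_per_site <- 0
    if (h > 1) for (a in 1:(h - 1)) for (b in (a + 1):h) {
      ok <- reps[a, ] %in% VALID_BASES & reps[b, ] %in% VALID_BASES
      Lab <- sum(ok)
      if (Lab == 0L)
        coihap_error("coihap_data_error",
                     "a sequence pair shares no usable column")
      d <- sum(reps[a, ok] != reps[b, ok])
      total_diff <- total_diff + f[a] * f[b] * d
      total_per_site <- total_per_site + f[a] * f[b] * d / Lab
    }
    k_hat <- total_diff / npairs
    pi <- total_per_site / npairs
    valid_count <- apply(mat, 2, function(col) sum(col %in% VALID_BASES))
    seg <- sum(apply(mat, 2, function(col) {
      v <- col[col %in% VALID_BASES]
      length(unique(v)) > 1
    }) & valid_count >= 2)
    L <- sum(valid_count >= 2)
  }
  list(n = n, h = tab$h, k_hat = k_hat, pi = pi, S = as.integer(seg),
       sites_used = as.integer(L), table = tab)
}

#' Nucleotide diversity per site
#'
#' `pi = sum_{i<j} d_ij / (C(n,2) * L)` where `d_ij` counts differing used
#' columns. The reported standard deviation is the square root of the
#' total (stochastic + sampling) variance under the no-recombination model,
#' `V(pi) = (n+1)/(3(n-1)L) * pi + 2(n^2+n+3)/(9n(n-1)) * pi^2`.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param policy `"complete_deletion"` (default) or `"pairwise_deletion"`.
#' @return Named numeric vector `c(pi =, pi_sd =, sites_used =)`.
#' @export
nucleotide_diversity <- function(seqs, policy = "complete_deletion") {
  st <- pairwise_diff_stats(seqs, policy)
  n <- st$n; L <- st$sites_used; pi <- st$pi
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  c(pi = pi, pi_sd = sqrt(max(v, 0)), sites_used = L)
}

#' Number of segregating sites
#'
#' @inheritParams nucleotide_diversity
#' @return Integer count of polymorphic used columns.
#' @export
segregating_sites <- function(seqs, policy = "complete_deletion") {
  pairwise_diff_stats(seqs, policy)$S
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (theta_pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants. Undefined (never silently 0) when there are no segregating
#' sites.
#'
#' @inheritParams nucleotide_diversity
#' @return A list of class `neutrality_stat` with `statistic` (`"D"`),
#'   `value` (`NA` when undefined), `defined`, `reason`, and the
#'   components `S`, `theta_pi` (mean pairwise differences per sequence)
#'   and `theta_w` (`S/a1`).
#' @export
tajimas_d <- function(seqs, policy = "complete_deletion") {
  st <- pairwise_diff_stats(seqs, policy)
  n <- st$n; S <- st$S; k <- st$k_hat
  if (S == 0L)
    return(structure(list(statistic = "D", value = NA_real_,
                          defined = FALSE,
                          reason = "no segregating sites",
                          S = S, theta_pi = k, theta_w = 0),
                     class = "neutrality_stat"))
  cs <- tajima_constants(n)
  d <- (k - S / cs$a1) / sqrt(cs$e1 * S + cs$e2 * S * (S - 1))
  structure(list(statistic = "D", value = d, defined = TRUE, reason = NULL,
                 S = S, theta_pi = k, theta_w = S / cs$a1),
            class = "neutrality_stat")
}

#' Distribution of the number of alleles under the Ewens sampling formula
#'
#' `Pr(K = k) = |s(n, k)| theta^k / (theta (theta+1) ... (theta+n-1))`,
#' with `|s(n, k)|` the unsigned Stirling numbers of the first kind,
#' computed by the standard recurrence in log space.
#'
#' @param n Sample size (`>= 1`).
#' @param theta Scaled mutation rate (`> 0`).
#' @return Numeric probability vector over `K = 1..n` (sums to 1 within
#'   1e-12 up to at least n = 200).
#' @examples
#' ewens_k_distribution(4, 1) # 6/24 11/24 6/24 1/24
#' @export
ewens_k_distribution <- function(n, theta) {
  n <- as.integer(n)
  if (n < 1L) coihap_error("coihap_config_error", "n must be >= 1")
  if (!is.finite(theta) || theta <= 0)
    coihap_error("coihap_config_error", "theta must be > 0")
  lp <- log_ewens_k(n, theta)
  exp(lp)
}

log_stirling1_row <- function(n) {
  lr <- 0 # |s(1,1)| = 1
  if (n == 1L) return(lr)
  for (m in 2:n) {
    prev <- lr
    lr <- numeric(m)
    lr[1] <- log(m - 1) + prev[1]
    if (m > 2L) {
      k <- 2:(m - 1)
      lr[k] <- logaddexp(log(m - 1) + prev[k], prev[k - 1])
    }
    lr[m] <- 0
  }
  lr
}

log_ewens_k <- function(n, theta) {
  ls <- log_stirling1_row(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  lp
}

#' Fu's Fs
#'
#' `Fs = ln(S' / (1 - S'))` where `S' = Pr(K >= k_obs)` under the Ewens
#' sampling formula evaluated at `theta = theta_pi`, the observed mean
#' number of pairwise differences per sequence (not per site), and `k_obs`
#' is the observed number of haplotypes. Strongly negative values indicate
#' an excess of rare alleles, as produced by demographic expansion.
#' Undefined when there is no nucleotide variation.
#'
#' @inheritParams nucleotide_diversity
#' @return A list of class `neutrality_stat` with `statistic` (`"Fs"`),
#'   `value`, `defined`, `reason`, `theta_pi`, `k_obs` and `s_prime`.
#' @export
fus_fs <- function(seqs, policy = "complete_deletion") {
  st <- pairwise_diff_stats(seqs, policy)
  n <- st$n; k_obs <- st$h; theta <- st$k_hat
  if (theta <= 0 || k_obs <= 1L)
    return(structure(list(statistic = "Fs", value = NA_real_,
                          defined = FALSE,
                          reason = "no nucleotide variation",
                          theta_pi = theta, k_obs = k_obs,
                          s_prime = NA_real_),
                     class = "neutrality_stat"))
  lp <- log_ewens_k(n, theta)
  log_sp <- logsumexp(lp[k_obs:n])
  log_1msp <- if (k_obs == 1L) -Inf else logsumexp(lp[1:(k_obs - 1L)])
  fs <- log_sp - log_1msp
  structure(list(statistic = "Fs", value = fs, defined = TRUE, reason = NULL,
                 theta_pi = theta, k_obs = k_obs, s_prime = exp(log_sp)),
            class = "neutrality_stat")
}

#' @export
print.neutrality_stat <- function(x, ...) {
  if (x$defined)
    cat(sprintf("%s = %.5f\n", x$statistic, x$value))
  else
    cat(sprintf("%s undefined: %s\n", x$statistic, x$reason))
  invisible(x)
}

#' All diversity and neutrality statistics for one population
#'
#' Convenience wrapper returning `n`, `h`, `Hd` (+- SD), `pi` (+- SD), `S`,
#' Tajima's `D` and Fu's `Fs` in one object. Undefined statistics carry
#' `NA` values plus an explicit reason; they are never reported as 0.
#'
#' @inheritParams nucleotide_diversity
#' @return An object of class `diversity_stats` (also a list).
#' @export
diversity_stats <- function(seqs, policy = "complete_deletion") {
  st <- pairwise_diff_stats(seqs, policy)
  hd <- haplotype_diversity(st$table)
  pv <- nucleotide_diversity(seqs, policy)
  d <- tajimas_d(seqs, policy)
  fs <- fus_fs(seqs, policy)
  structure(list(n = st$n, h = st$h,
                 Hd = unname(hd["Hd"]), Hd_sd = unname(hd["Hd_sd"]),
                 pi = unname(pv["pi"]), pi_sd = unname(pv["pi_sd"]),
                 S = st$S, sites_used = st$sites_used,
                 theta_pi = st$k_hat,
                 tajima_d = d$value, tajima_d_defined = d$defined,
                 fu_fs = fs$value, fu_fs_defined = fs$defined,
                 policy = policy),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, digits = 4, ...) {
  cat(sprintf("Population summary (n = %d, %d sites used, %s)\n",
              x$n, x$sites_used, x$policy))
  cat(sprintf("  haplotypes h        : %d\n", x$h))
  cat(sprintf("  Hd (+- SD)          : %.*f +- %.*f\n", digits, x$Hd,
              digits, x$Hd_sd))
  cat(sprintf("  pi per site (+- SD) : %.*f +- %.*f\n", digits, x$pi,
              digits, x$pi_sd))
  cat(sprintf("  segregating sites S : %d\n", x$S))
  cat(sprintf("  Tajima's D          : %s\n",
              if (x$tajima_d_defined) sprintf("%.5f", x$tajima_d) else "undefined"))
  cat(sprintf("  Fu's Fs             : %s\n",
              if (x$fu_fs_defined) sprintf("%.4f", x$fu_fs) else "undefined"))
  invisible(x)
}
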