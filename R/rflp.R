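# In-silico PCR-RFLP: primer search, amplicon extraction, restriction
# digestion and diagnostic pattern classification.

# Number of mismatches between an IUPAC pattern and a concrete window.
# A pattern ambiguity code matches any base it denotes; the window is taken
# literally.
iupac_mismatch_count <- function(pattern_chars, window_chars) {
  sum(!mapply(function(p, w) w %in% IUPAC_SETS[[p]],
              pattern_chars, window_chars))
}

#' Find primer annealing sites
#'
#' Scans both strands of a sequence for matches of an IUPAC primer with at
#' most `max_mismatch` mismatches. Ambiguity codes in the primer match any
#' base they denote; the subject sequence is taken literally. Minus-strand
#' hits are matches of the primer's reverse complement, reported in
#' plus-strand coordinates.
#'
#' @param sequence A nucleotide string.
#' @param primer IUPAC primer string.
#' @param max_mismatch Maximum number of mismatches (default 0).
#' @return A data.frame with columns `strand` (`"+"`/`"-"`), `start`
#'   (0-based plus-strand offset of the matched window) and `mismatches`,
#'   sorted by position. Zero rows when there is no hit.
#' @export
find_primer_sites <- function(sequence, primer, max_mismatch = 0L) {
  sequence <- toupper(sequence)
  primer <- toupper(primer)
  if (nchar(primer) < 4L)
    coihap_error("coihap_config_error", "primer must be at least 4 bases long")
  subject <- Biostrings::DNAString(sequence)
  scan_one <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                     max.mismatch = max_mismatch,
                                     fixed = "subject")
    starts <- BiocGenerics::start(hits)
    if (length(starts) == 0L) return(NULL)
    pat_chars <- strsplit(pat, "", fixed = TRUE)[[1]]
    seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    mm <- vapply(starts, function(s)
      iupac_mismatch_count(pat_chars,
                           seq_chars[s:(s + length(pat_chars) - 1L)]),
      integer(1))
    data.frame(strand = strand, start = starts - 1L, mismatches = mm)
  }
  res <- rbind(
    scan_one(primer, "+"),
    scan_one(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(primer))), "-")
  )
  if (is.null(res))
    return(data.frame(strand = character(0), start = integer(0),
                      mismatches = integer(0)))
  res <- res[res$mismatches <= max_mismatch, , drop = FALSE]
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract a PCR amplicon delimited by two primers
#'
#' The amplicon spans from the first base of the forward-primer hit to the
#' last base of the reverse-primer hit, primers included (the convention
#' under which a published amplicon length such as 866 bp counts both primer
#' footprints). When several primer-hit pairs exist, the pair whose product
#' length is nearest `expected_length` is chosen. An input that already has
#' the expected length and carries no primer hit is passed through unchanged
#' and flagged as a pre-cut amplicon, so pipelines can run on deposited
#' amplicon sequences without knowing the primers.
#'
#' @param sequence Template nucleotide string.
#' @param fwd_primer,rev_primer IUPAC primer strings; the reverse primer is
#'   given 5'->3' on the minus strand, as usual.
#' @param max_mismatch Maximum mismatches per primer (default 1).
#' @param expected_length Expected product length in bp (default 866).
#' @param tolerance Acceptable deviation from `expected_length` (default 50).
#' @param id Optional specimen id carried through to the result.
#' @return An object of class `amplicon`: list with `specimen_id`,
#'   `sequence`, `interval` (0-based half-open on the input),
#'   `primer_mismatches` (forward, reverse) and `pre_cut` flag.
#' @export
extract_amplicon <- function(sequence, fwd_primer, rev_primer,
                             max_mismatch = 1L, expected_length = 866L,
                             tolerance = 50L, id = NULL) {
  sequence <- degap(toupper(sequence))
  fwd <- find_primer_sites(sequence, fwd_primer, max_mismatch)
  fwd <- fwd[fwd$strand == "+", , drop = FALSE]
  rev <- find_primer_sites(sequence, rev_primer, max_mismatch)
  rev <- rev[rev$strand == "-", , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    if (nchar(sequence) == expected_length) {
      message(sprintf("extract_amplicon: no primer hits for '%s'; input of expected length passed through as pre-cut amplicon",
                      id %||% "<unnamed>"))
      return(structure(list(specimen_id = id, sequence = sequence,
                            interval = c(0L, nchar(sequence)),
                            primer_mismatches = c(NA_integer_, NA_integer_),
                            pre_cut = TRUE),
                       class = "amplicon"))
    }
    coihap_error("coihap_extraction_error",
                 paste0("no valid primer pair for specimen '",
                        id %||% "<unnamed>", "'"))
  }
  rev_len <- nchar(rev_primer)
  pairs <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  pairs$len <- rev$start[pairs$r] + rev_len - fwd$start[pairs$f]
  pairs <- pairs[pairs$len >= nchar(fwd_primer) + rev_len, , drop = FALSE]
  pairs <- pairs[abs(pairs$len - expected_length) <= tolerance, , drop = FALSE]
  if (nrow(pairs) == 0L)
    coihap_error("coihap_extraction_error",
                 paste0("no primer pair yields a product within ", tolerance,
                        " bp of ", expected_length, " for specimen '",
                        id %||% "<unnamed>", "'"))
  pairs <- pairs[order(abs(pairs$len - expected_length),
                       fwd$start[pairs$f]), , drop = FALSE]
  best <- pairs[1, ]
  from0 <- fwd$start[best$f]
  to0 <- rev$start[best$r] + rev_len
  structure(list(specimen_id = id,
                 sequence = substr(sequence, from0 + 1L, to0),
                 interval = c(from0, to0),
                 primer_mismatches = c(fwd$mismatches[best$f],
                                       rev$mismatches[best$r]),
                 pre_cut = FALSE),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("Amplicon%s: %d bp at [%d, %d)%s\n",
              if (is.null(x$specimen_id)) "" else paste0(" ", x$specimen_id),
              nchar(x$sequence), x$interval[1], x$interval[2],
              if (isTRUE(x$pre_cut)) " (pre-cut input)" else ""))
  invisible(x)
}

#' Digest an amplicon with a restriction enzyme
#'
#' Finds every plus-strand occurrence of the enzyme's recognition sequence
#' and reports cut positions as prefix lengths (`match start + cut offset`).
#' Overlapping recognition matches each contribute a cut; duplicate cut
#' positions collapse. Fragment lengths are successive differences between
#' cut points, including the two end pieces, so they always sum to the
#' amplicon length. Cuts falling exactly at position 0 or at the amplicon
#' end produce no fragment boundary and are dropped.
#'
#' The amplicon must be unambiguous (A/C/G/T only): ambiguity codes make the
#' presence of a site undecidable and raise an error naming the position.
#'
#' @param amplicon Nucleotide string, or an `amplicon` object.
#' @param enzyme An `enzyme_spec`, default [apoi()].
#' @param id Optional specimen id.
#' @return An object of class `digest_result` with fields `specimen_id`,
#'   `amplicon_length`, `cut_positions` (sorted prefix lengths) and
#'   `fragments` (sorted lengths).
#' @examples
#' d <- digest_sequence("AAAAGAATTTCCCC")
#' d$cut_positions # 5
#' d$fragments     # 5 9
#' @export
digest_sequence <- function(amplicon, enzyme = apoi(), id = NULL) {
  if (inherits(amplicon, "amplicon")) {
    id <- id %||% amplicon$specimen_id
    amplicon <- amplicon$sequence
  }
  amplicon <- toupper(amplicon)
  chars <- strsplit(amplicon, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    coihap_error("coihap_digest_error",
                 sprintf("ambiguous or illegal base '%s' at position %d: site status undecidable",
                         chars[bad[1]], bad[1]))
  len <- nchar(amplicon)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(enzyme$recognition),
                                   Biostrings::DNAString(amplicon),
                                   fixed = "subject")
  cuts <- sort(unique(BiocGenerics::start(hits) - 1L + enzyme$cut_offset))
  cuts <- cuts[cuts > 0L & cuts < len]
  fragments <- sort(diff(c(0L, cuts, len)))
  stopifnot(sum(fragments) == len,
            length(fragments) == length(cuts) + 1L,
            all(fragments >= 1L))
  structure(list(specimen_id = id, amplicon_length = len,
                 cut_positions = cuts, fragments = fragments,
                 enzyme = enzyme$name),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("%s digest%s of %d bp amplicon\n", x$enzyme,
              if (is.null(x$specimen_id)) "" else paste0(" (", x$specimen_id, ")"),
              x$amplicon_length))
  cat("  cut positions:", if (length(x$cut_positions))
    paste(x$cut_positions, collapse = ", ") else "none", "\n")
  cat("  fragments (bp):", paste(x$fragments, collapse = ", "), "\n")
  invisible(x)
}
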