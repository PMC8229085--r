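# Diagnostic RFLP pattern library and classification.

#' Define a diagnostic RFLP pattern
#'
#' A pattern ties a taxon/haplogroup label to the set of cut positions
#' (prefix lengths) expected on a reference amplicon; the expected fragment
#' multiset is derived from the cut positions, which guarantees the two are
#' mutually consistent and that fragments sum to the amplicon length.
#'
#' @param label Pattern label (e.g. `"MEDQ1"`).
#' @param cut_positions Integer vector of plus-strand cut prefix lengths,
#'   strictly inside `(0, amplicon_length)`.
#' @param amplicon_length Reference amplicon length in bp (default 866).
#' @return An object of class `rflp_pattern`.
#' @export
rflp_pattern <- function(label, cut_positions, amplicon_length = 866L) {
  cut_positions <- sort(unique(as.integer(cut_positions)))
  if (length(cut_positions) &&
      (min(cut_positions) <= 0L || max(cut_positions) >= amplicon_length))
    coihap_error("coihap_config_error",
                 paste0("cut positions of pattern '", label,
                        "' must lie strictly inside (0, ", amplicon_length, ")"))
  fragments <- sort(diff(c(0L, cut_positions, as.integer(amplicon_length))))
  structure(list(label = label, cut_positions = cut_positions,
                 amplicon_length = as.integer(amplicon_length),
                 expected_fragments = fragments),
            class = "rflp_pattern")
}

#' Assemble a pattern library
#'
#' Validates that labels are unique and that each pattern's expected
#' fragments regenerate from its cut positions (checked by construction in
#' [rflp_pattern()], re-asserted here as the load-time self-consistency
#' check).
#'
#' @param ... `rflp_pattern` objects, or a single list of them.
#' @return An object of class `pattern_library`.
#' @export
pattern_library <- function(...) {
  pats <- list(...)
  if (length(pats) == 1L && !inherits(pats[[1]], "rflp_pattern"))
    pats <- pats[[1]]
  if (length(pats) == 0L)
    coihap_error("coihap_config_error", "pattern library is empty")
  if (!all(vapply(pats, inherits, logical(1), "rflp_pattern")))
    coihap_error("coihap_config_error", "all entries must be rflp_pattern objects")
  labels <- vapply(pats, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    coihap_error("coihap_config_error", "pattern labels must be unique")
  for (p in pats) {
    regen <- sort(diff(c(0L, p$cut_positions, p$amplicon_length)))
    if (!identical(regen, p$expected_fragments) ||
        sum(p$expected_fragments) != p$amplicon_length)
      coihap_error("coihap_config_error",
                   paste0("pattern '", p$label, "' is internally inconsistent"))
  }
  names(pats) <- labels
  structure(pats, class = "pattern_library")
}

#' Built-in MED haplogroup ApoI pattern library
#'
#' The three diagnostic ApoI patterns for the 866-bp COI amplicon of
#' *Bemisia tabaci* MED: MEDQ1 (cuts at 252, 296, 562, 654), the Sardinian
#' MEDQ1 variant with an additional site at 672, and MEDQ2 (cuts at
#' 252, 296, 654). The MEAM1 pattern is deliberately not built in: its cut
#' positions are assay-specific and must be supplied by the user via
#' [rflp_pattern()] when needed.
#'
#' @return A `pattern_library`.
#' @examples
#' lib <- med_pattern_library()
#' lib$MEDQ1$expected_fragments # 44 92 212 252 266
#' @export
med_pattern_library <- function() {
  pattern_library(
    rflp_pattern("MEDQ1", c(252L, 296L, 562L, 654L), 866L),
    rflp_pattern("MEDQ1-Sardinian", c(252L, 296L, 562L, 654L, 672L), 866L),
    rflp_pattern("MEDQ2", c(252L, 296L, 654L), 866L)
  )
}

#' @export
print.pattern_library <- function(x, ...) {
  cat(sprintf("RFLP pattern library (%d patterns)\n", length(x)))
  for (p in x)
    cat(sprintf("  %-16s cuts {%s} -> fragments {%s} (sum %d)\n", p$label,
                paste(p$cut_positions, collapse = ", "),
                paste(p$expected_fragments, collapse = ", "),
                sum(p$expected_fragments)))
  invisible(x)
}

# multiset distance: size of the symmetric difference of two integer multisets
multiset_distance <- function(a, b) {
  vals <- union(a, b)
  sum(vapply(vals, function(v) abs(sum(a == v) - sum(b == v)), numeric(1)))
}

set_distance <- function(a, b) length(union(a, b)) - length(intersect(a, b))

#' Classify a digest against a pattern library
#'
#' Three match modes are supported. `cut_set_exact` (the default for
#' sequence-derived digests) matches on identical cut-position sets;
#' `fragment_multiset` on identical fragment multisets;
#' `gel_visible_fragments` on fragment multisets after discarding, from both
#' the digest and each library pattern, fragments shorter than
#' `gel_min_visible` bp -- mimicking reading a stained gel on which small
#' fragments run off or are too faint to see. A digest is classified only on
#' a perfect (distance 0) match; otherwise the label is `"unclassified"`
#' and the nearest pattern is reported. Distance-0 ties also yield
#' `"unclassified"`, with both candidates recorded.
#'
#' @param digest A `digest_result`.
#' @param library A `pattern_library`.
#' @param mode One of `"cut_set_exact"`, `"fragment_multiset"`,
#'   `"gel_visible_fragments"`.
#' @param gel_min_visible Smallest gel-visible fragment in bp (default 25).
#' @return An object of class `classification_result` with fields
#'   `specimen_id`, `label`, `match_mode`, `distance_to_best` and
#'   `runner_up` (label and distance, or `NULL`).
#' @export
classify_pattern <- function(digest, library,
                             mode = c("cut_set_exact", "fragment_multiset",
                                      "gel_visible_fragments"),
                             gel_min_visible = 25L) {
  mode <- match.arg(mode)
  if (!inherits(library, "pattern_library") || length(library) == 0L)
    coihap_error("coihap_config_error", "a non-empty pattern_library is required")
  dist_to <- function(p) {
    switch(mode,
      cut_set_exact = set_distance(digest$cut_positions, p$cut_positions),
      fragment_multiset = multiset_distance(digest$fragments,
                                            p$expected_fragments),
      gel_visible_fragments = multiset_distance(
        digest$fragments[digest$fragments >= gel_min_visible],
        p$expected_fragments[p$expected_fragments >= gel_min_visible]))
  }
  d <- vapply(library, dist_to, numeric(1))
  ord <- order(d, names(d))
  best <- ord[1]
  runner <- if (length(d) > 1L)
    list(label = names(d)[ord[2]], distance = unname(d[ord[2]])) else NULL
  tie <- d[best] == 0 && length(d) > 1L && d[ord[2]] == 0
  if (tie)
    message(sprintf("classify_pattern: distance-0 tie between '%s' and '%s'; reporting unclassified",
                    names(d)[ord[1]], names(d)[ord[2]]))
  label <- if (d[best] == 0 && !tie) names(d)[best] else "unclassified"
  structure(list(specimen_id = digest$specimen_id, label = label,
                 match_mode = mode, distance_to_best = unname(d[best]),
                 runner_up = runner),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s -> %s [%s, distance %g]%s\n",
              x$specimen_id %||% "<unnamed>", x$label, x$match_mode,
              x$distance_to_best,
              if (is.null(x$runner_up)) "" else
                sprintf(" (runner-up %s at %g)", x$runner_up$label,
                        x$runner_up$distance)))
  invisible(x)
}

#' Classify a set of specimens by in-silico PCR-RFLP
#'
#' Runs amplicon extraction (when primers are given; otherwise inputs are
#' treated as pre-cut amplicons), restriction digestion and pattern
#' classification over a set of sequences. Specimens whose extraction or
#' digestion fails are reported with label `NA` and the failure stage.
#'
#' @param seqs Named character vector of sequences, or a specimen
#'   data.frame with `specimen_id` and `sequence` columns.
#' @param library A `pattern_library` (default [med_pattern_library()]).
#' @param enzyme An `enzyme_spec` (default [apoi()]).
#' @param fwd_primer,rev_primer Optional primer strings; when `NULL` the
#'   inputs must already be amplicons.
#' @param max_mismatch,expected_length,tolerance Passed to
#'   [extract_amplicon()].
#' @param mode,gel_min_visible Passed to [classify_pattern()].
#' @return A data.frame with one row per specimen: `specimen_id`, `label`,
#'   `mode`, `distance`, `runner_up`, `stage_failed` (`NA` when typing
#'   succeeded). The extracted amplicon sequences are attached as attribute
#'   `"amplicons"` (a named character vector over the successfully typed
#'   specimens) so downstream stages can operate on the amplicons rather
#'   than the raw inputs.
#' @export
classify_specimens <- function(seqs, library = med_pattern_library(),
                               enzyme = apoi(),
                               fwd_primer = NULL, rev_primer = NULL,
                               max_mismatch = 1L, expected_length = 866L,
                               tolerance = 50L,
                               mode = "cut_set_exact", gel_min_visible = 25L) {
  seqs <- degap(as_seq_vector(seqs))
  amplicons <- character(0)
  rows <- lapply(names(seqs), function(id) {
    amp <- tryCatch({
      if (is.null(fwd_primer) || is.null(rev_primer))
        structure(list(specimen_id = id, sequence = seqs[[id]],
                       interval = c(0L, nchar(seqs[[id]])),
                       primer_mismatches = c(NA_integer_, NA_integer_),
                       pre_cut = TRUE), class = "amplicon")
      else
        extract_amplicon(seqs[[id]], fwd_primer, rev_primer,
                         max_mismatch = max_mismatch,
                         expected_length = expected_length,
                         tolerance = tolerance, id = id)
    }, coihap_error = function(e) e)
    if (inherits(amp, "error"))
      return(data.frame(specimen_id = id, label = NA_character_,
                        mode = mode, distance = NA_real_,
                        runner_up = NA_character_,
                        stage_failed = "extraction"))
    dig <- tryCatch(digest_sequence(amp, enzyme), coihap_error = function(e) e)
    if (inherits(dig, "error"))
      return(data.frame(specimen_id = id, label = NA_character_,
                        mode = mode, distance = NA_real_,
                        runner_up = NA_character_,
                        stage_failed = "digestion"))
    cl <- classify_pattern(dig, library, mode = mode,
                           gel_min_visible = gel_min_visible)
    amplicons[[id]] <<- amp$sequence
    data.frame(specimen_id = id, label = cl$label, mode = mode,
               distance = cl$distance_to_best,
               runner_up = if (is.null(cl$runner_up)) NA_character_ else
                 sprintf("%s:%g", cl$runner_up$label, cl$runner_up$distance),
               stage_failed = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "amplicons") <- amplicons
  out
}
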