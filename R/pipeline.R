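# Pipeline driver: classify -> collapse -> statistics -> network -> tree
# from a single validated configuration, plus the survey-style composition
# report.

PIPELINE_KEYS <- c("fasta", "metadata", "fwd_primer", "rev_primer",
                   "max_mismatch", "expected_length", "tolerance",
                   "enzyme", "patterns", "comparison_policy", "epsilon",
                   "match_mode", "gel_min_visible", "group_by", "seed",
                   "out_dir", "min_group_size")

#' Build and validate a pipeline configuration
#'
#' @param fasta,metadata Input FASTA and metadata TSV paths.
#' @param fwd_primer,rev_primer Optional primers; when omitted, inputs must
#'   already be amplicons of `expected_length` (the pre-cut bypass).
#' @param max_mismatch,expected_length,tolerance Amplicon-extraction
#'   parameters (defaults 1, 866, 50).
#' @param enzyme An `enzyme_spec` (default [apoi()]).
#' @param patterns A `pattern_library` (default [med_pattern_library()]).
#' @param comparison_policy Column policy for the popgen stage.
#' @param epsilon Median-joining relaxation (default 0).
#' @param match_mode Classification mode (default `cut_set_exact`).
#' @param gel_min_visible Smallest gel-visible fragment (default 25).
#' @param group_by Metadata/classification keys for the popgen grouping and
#'   the composition report (default `c("label", "region")`).
#' @param min_group_size Smallest group analysed in the popgen/network
#'   stages (default 4).
#' @param seed Seed recorded in the manifest (stages are deterministic).
#' @param out_dir Output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, metadata, fwd_primer = NULL,
                            rev_primer = NULL, max_mismatch = 1L,
                            expected_length = 866L, tolerance = 50L,
                            enzyme = apoi(), patterns = med_pattern_library(),
                            comparison_policy = "complete_deletion",
                            epsilon = 0L, match_mode = "cut_set_exact",
                            gel_min_visible = 25L,
                            group_by = c("label", "region"),
                            min_group_size = 4L, seed = 1L,
                            out_dir = "coihap_out") {
  cfg <- list(fasta = fasta, metadata = metadata, fwd_primer = fwd_primer,
              rev_primer = rev_primer, max_mismatch = as.integer(max_mismatch),
              expected_length = as.integer(expected_length),
              tolerance = as.integer(tolerance), enzyme = enzyme,
              patterns = patterns, comparison_policy = comparison_policy,
              epsilon = as.integer(epsilon), match_mode = match_mode,
              gel_min_visible = as.integer(gel_min_visible),
              group_by = group_by, min_group_size = as.integer(min_group_size),
              seed = as.integer(seed), out_dir = out_dir)
  check_policy(comparison_policy)
  if (!inherits(cfg$enzyme, "enzyme_spec"))
    coihap_error("coihap_config_error", "enzyme must be an enzyme_spec")
  if (!inherits(cfg$patterns, "pattern_library"))
    coihap_error("coihap_config_error", "patterns must be a pattern_library")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys are those of [pipeline_config()]; `enzyme` may be given
#' as `{name, recognition, cut_offset}` and `patterns` as a map of
#' `label: [cut positions]` (with optional `amplicon_length`). Unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c(PIPELINE_KEYS, "amplicon_length"))
  if (length(unknown))
    coihap_error("coihap_config_error",
                 paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  if (!is.null(raw$enzyme))
    raw$enzyme <- restriction_enzyme(raw$enzyme$name, raw$enzyme$recognition,
                                     raw$enzyme$cut_offset)
  if (!is.null(raw$patterns)) {
    alen <- raw$amplicon_length %||% 866L
    raw$patterns <- pattern_library(lapply(names(raw$patterns), function(lbl)
      rflp_pattern(lbl, unlist(raw$patterns[[lbl]]), alen)))
  }
  raw$amplicon_length <- NULL
  do.call(pipeline_config, raw)
}

#' Summarise the survey composition
#'
#' Counts classified specimens by the requested grouping keys (any of the
#' metadata columns plus `label`) and reports each label's percentage share
#' within every combination of the non-label keys. Unclassified and failed
#' specimens appear as their own rows and are never dropped silently.
#'
#' @param classifications Data.frame from [classify_specimens()].
#' @param metadata Metadata data.frame (joined on `specimen_id`).
#' @param group_by Character vector of grouping keys, `"label"` plus
#'   metadata columns (default `c("region", "label")`).
#' @return An object of class `region_summary`: data.frame of counts and
#'   percentages with attribute `total`.
#' @export
summarize_composition <- function(classifications, metadata,
                                  group_by = c("region", "label")) {
  df <- merge(classifications, metadata, by = "specimen_id", all.x = TRUE)
  df$label[is.na(df$label)] <- "failed"
  missing <- setdiff(group_by, c(names(df)))
  if (length(missing))
    coihap_error("coihap_config_error",
                 paste0("grouping key(s) absent from metadata: ",
                        paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) {
    out <- stats::setNames(
      data.frame(matrix(ncol = length(group_by) + 2L, nrow = 0L)),
      c(group_by, "count", "percent"))
    attr(out, "total") <- 0L
    class(out) <- c("region_summary", "data.frame")
    return(out)
  }
  counts <- aggregate(list(count = rep(1L, nrow(df))),
                      by = df[, group_by, drop = FALSE], FUN = sum)
  outer_keys <- setdiff(group_by, "label")
  if (length(outer_keys) == 0L) {
    counts$percent <- round(100 * counts$count / sum(counts$count), 1)
  } else {
    grp <- interaction(counts[, outer_keys, drop = FALSE], drop = TRUE)
    totals <- tapply(counts$count, grp, sum)
    counts$percent <- round(100 * counts$count / as.numeric(totals[grp]), 1)
  }
  counts <- counts[do.call(order, counts[group_by]), , drop = FALSE]
  rownames(counts) <- NULL
  attr(counts, "total") <- sum(counts$count)
  class(counts) <- c("region_summary", "data.frame")
  counts
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Survey composition (%d specimens)\n", attr(x, "total")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Run the full typing-and-genetics pipeline
#'
#' Reads sequences and metadata, classifies every specimen by in-silico
#' PCR-RFLP, computes diversity and neutrality statistics per group,
#' builds a median-joining network and a neighbor-joining tree per
#' haplogroup with enough haplotypes, writes the survey composition report,
#' and records a JSON manifest (config echo, versions, seed, per-stage
#' counts, specimen-conservation check). Re-running with the same inputs
#' and config reproduces every artifact byte for byte, except for the
#' manifest timestamp.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the output paths and in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    coihap_error("coihap_config_error", "config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(config$fasta)
  meta <- read_metadata(config$metadata)
  specimens <- join_specimens(seqs, meta)
  if (nrow(specimens) == 0L)
    coihap_error("coihap_data_error", "no specimens to analyse")

  cls <- classify_specimens(
    stats::setNames(specimens$sequence, specimens$specimen_id),
    library = config$patterns, enzyme = config$enzyme,
    fwd_primer = config$fwd_primer, rev_primer = config$rev_primer,
    max_mismatch = config$max_mismatch,
    expected_length = config$expected_length, tolerance = config$tolerance,
    mode = config$match_mode, gel_min_visible = config$gel_min_visible)
  cls_path <- file.path(out, "classification.tsv")
  write.table(cls, cls_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # downstream stages operate on the extracted amplicons, not raw inputs
  amplicons <- attr(cls, "amplicons")
  merged <- merge(cls, meta, by = "specimen_id")
  merged$sequence <- unname(amplicons[merged$specimen_id])
  ok <- !is.na(merged$label) & merged$label != "unclassified"
  groups <- split(merged[ok, , drop = FALSE], merged$label[ok])

  popgen <- list()
  network_files <- character(0)
  for (lbl in names(groups)) {
    g <- groups[[lbl]]
    if (nrow(g) < config$min_group_size) next
    seqs_g <- stats::setNames(g$sequence, g$specimen_id)
    stats_g <- diversity_stats(seqs_g, config$comparison_policy)
    popgen[[lbl]] <- unclass(stats_g)
    tab <- collapse_haplotypes(seqs_g)
    if (tab$h >= 2L) {
      traits <- make_traits(tab, g, "region")
      net <- median_joining(tab, epsilon = config$epsilon, traits = traits)
      for (fmt in c("graphml", "nexus", "edgelist")) {
        ext <- c(graphml = "graphml", nexus = "nex", edgelist = "edges.tsv")[fmt]
        p <- file.path(out, sprintf("network_%s.%s", gsub("[^A-Za-z0-9_-]", "_", lbl), ext))
        export_network(net, p, fmt)
        network_files <- c(network_files, p)
      }
    }
  }
  popgen_path <- file.path(out, "popgen.json")
  jsonlite::write_json(popgen, popgen_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  popgen_tsv <- file.path(out, "popgen.tsv")
  if (length(popgen)) {
    pg <- do.call(rbind, lapply(names(popgen), function(lbl) {
      s <- popgen[[lbl]]
      data.frame(group = lbl, n = s$n, h = s$h, Hd = s$Hd, Hd_sd = s$Hd_sd,
                 pi = s$pi, pi_sd = s$pi_sd, S = s$S,
                 tajima_d = ifelse(s$tajima_d_defined, s$tajima_d, NA),
                 fu_fs = ifelse(s$fu_fs_defined, s$fu_fs, NA))
    }))
    write.table(pg, popgen_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tree_path <- NULL
  hap_all <- tryCatch(collapse_haplotypes(
    stats::setNames(merged$sequence[ok],
                    paste(merged$label[ok],
                          merged$specimen_id[ok], sep = "|"))),
    coihap_error = function(e) NULL)
  if (!is.null(hap_all) && hap_all$h >= 3L) {
    reps <- stats::setNames(hap_all$haplotypes$sequence,
                            vapply(hap_all$members, `[[`, character(1), 1))
    D <- tn93_matrix(reps)
    if (!any(is.na(D))) {
      tree_path <- file.path(out, "tree.nwk")
      write_newick(nj_tree(D), tree_path)
    }
  }

  report <- summarize_composition(cls, meta, config$group_by)
  report_path <- file.path(out, "composition.tsv")
  write.table(report, report_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  n_failed_extract <- sum(cls$stage_failed %in% "extraction")
  n_failed_digest <- sum(cls$stage_failed %in% "digestion")
  n_classified <- sum(is.na(cls$stage_failed))
  stopifnot(nrow(cls) == n_classified + n_failed_extract + n_failed_digest)
  manifest <- list(
    package = "coihap",
    version = as.character(packageVersion("coihap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    inputs = list(fasta = config$fasta, metadata = config$metadata),
    settings = list(
      enzyme = config$enzyme$name,
      recognition = config$enzyme$recognition,
      match_mode = config$match_mode,
      comparison_policy = config$comparison_policy,
      epsilon = config$epsilon,
      group_by = config$group_by),
    counts = list(n_input = nrow(cls),
                  n_classified = n_classified,
                  n_extraction_failed = n_failed_extract,
                  n_digestion_failed = n_failed_digest,
                  n_unclassified = sum(cls$label %in% "unclassified")))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(classification = cls_path, popgen = popgen_path,
                 popgen_tsv = popgen_tsv, networks = network_files,
                 tree = tree_path, composition = report_path,
                 manifest = manifest_path,
                 results = list(classifications = cls, popgen = popgen,
                                composition = report)))
}

make_traits <- function(tab, group_df, key) {
  if (!key %in% names(group_df)) return(NULL)
  rows <- list()
  for (hap in names(tab$members)) {
    vals <- group_df[[key]][match(tab$members[[hap]], group_df$specimen_id)]
    t <- table(vals)
    for (g in names(t))
      rows[[length(rows) + 1]] <- data.frame(haplotype_id = hap, group = g,
                                             count = as.integer(t[[g]]))
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}
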