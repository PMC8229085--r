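#' Read a multi-record FASTA file
#'
#' Record ids are taken from the header token before the first whitespace,
#' sequences are uppercased and line breaks within a record are joined.
#' Sequences must be drawn from the IUPAC nucleotide alphabet (plus the gap
#' character `-`); any other character is a parse error naming the offending
#' record and line.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are record ids),
#'   in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    coihap_error("coihap_io_error", paste0("file not found: ", path))
  # Read permissively (BStringSet accepts any letters) so that alphabet
  # violations can be reported per record rather than as an opaque failure.
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    coihap_error("coihap_parse_error",
                                 paste0("malformed FASTA in ", path, ": ",
                                        conditionMessage(e))))
  if (length(set) == 0L)
    coihap_error("coihap_parse_error", paste0("no FASTA records in ", path))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == ""))
    coihap_error("coihap_parse_error",
                 paste0("empty FASTA header at record ",
                        which(ids == "")[1], " in ", path))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% IUPAC_LETTERS)
    if (length(bad)) {
      # locate the line for the error message
      lines <- readLines(path, warn = FALSE)
      hdr <- grep("^>", lines)
      rec_start <- hdr[i]
      coihap_error("coihap_parse_error",
                   sprintf(paste0("illegal character '%s' in sequence of ",
                                  "record '%s' (record starting at line %d)"),
                           chars[bad[1]], ids[i], rec_start))
    }
    if (!nzchar(seqs[i]))
      coihap_error("coihap_parse_error",
                   paste0("empty sequence for record '", ids[i], "'"))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_seq_vector(seqs)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

SETTING_LEVELS <- c("greenhouse", "open_field", "weed", "unknown")
METADATA_COLUMNS <- c("specimen_id", "region", "host_plant", "setting", "year")

#' Read a specimen metadata table
#'
#' Reads a tab-separated survey table with a header row containing at least
#' `specimen_id`, `region`, `host_plant`, `setting` and `year` (a `locality`
#' column is kept when present). Setting values outside
#' `greenhouse`/`open_field`/`weed` are mapped to `unknown` with a warning.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of specimen metadata stubs (no sequences).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    coihap_error("coihap_io_error", paste0("file not found: ", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(METADATA_COLUMNS, names(df))
  if (length(missing))
    coihap_error("coihap_config_error",
                 paste0("metadata table is missing mandatory column(s): ",
                        paste(missing, collapse = ", ")))
  df$specimen_id <- as.character(df$specimen_id)
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup))
    coihap_error("coihap_data_error",
                 paste0("duplicate specimen_id in metadata: ",
                        paste(unique(dup), collapse = ", ")))
  if (!"locality" %in% names(df)) df$locality <- NA_character_
  unknown <- !(df$setting %in% SETTING_LEVELS)
  if (any(unknown)) {
    warning(sprintf("%d specimen(s) with unrecognised setting value(s) (%s) mapped to 'unknown'",
                    sum(unknown),
                    paste(unique(df$setting[unknown]), collapse = ", ")),
            call. = FALSE)
    df$setting[unknown] <- "unknown"
  }
  df$year <- as.integer(df$year)
  df[, unique(c(METADATA_COLUMNS, "locality", names(df)))]
}

#' Write a specimen metadata table
#'
#' @param meta Data.frame as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Join sequences to specimen metadata
#'
#' Inner join on `specimen_id`; sequence ids are matched case-sensitively.
#' Counts of unmatched ids on both sides are reported via `message()`.
#'
#' @param seqs Named character vector of sequences.
#' @param meta Metadata data.frame with a `specimen_id` column.
#' @return A data.frame of specimen records (metadata columns plus
#'   `sequence`), one row per matched specimen, in sequence-file order.
#' @export
join_specimens <- function(seqs, meta) {
  seqs <- as_seq_vector(seqs)
  ids <- intersect(names(seqs), meta$specimen_id)
  if (length(ids) == 0L)
    coihap_error("coihap_data_error",
                 "no specimen_id shared between sequences and metadata")
  lost_seq <- setdiff(names(seqs), ids)
  lost_meta <- setdiff(meta$specimen_id, ids)
  if (length(lost_seq) || length(lost_meta))
    message(sprintf("join_specimens: %d sequence id(s) and %d metadata id(s) unmatched",
                    length(lost_seq), length(lost_meta)))
  keep <- names(seqs)[names(seqs) %in% ids]
  out <- meta[match(keep, meta$specimen_id), , drop = FALSE]
  out$sequence <- unname(seqs[keep])
  rownames(out) <- NULL
  out
}

# Strip alignment gaps before physical-assay operations (digestion, PCR).
degap <- function(seqs) gsub("-", "", seqs, fixed = TRUE)
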