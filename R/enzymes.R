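#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its IUPAC recognition sequence and the
#' plus-strand cut offset: the number of bases, 5' to 3', between the start of
#' the recognition site and the cut. Cut positions produced by
#' [digest_sequence()] are reported as prefix lengths (number of bases 5' of
#' the cut on the plus strand), the convention under which diagnostic RFLP
#' fragment sizes are usually published. Double-strand overhangs are ignored:
#' fragment lengths are distances between plus-strand cut points.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence using IUPAC nucleotide codes.
#' @param cut_offset Integer in `[0, nchar(recognition)]`; bases from the
#'   recognition-site start to the plus-strand cut.
#' @return An object of class `enzyme_spec`.
#' @examples
#' apoi()
#' restriction_enzyme("EcoRI", "GAATTC", 1)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  bad <- setdiff(strsplit(recognition, "")[[1]], names(IUPAC_SETS))
  if (length(bad))
    coihap_error("coihap_config_error",
                 paste0("recognition sequence contains non-IUPAC letters: ",
                        paste(bad, collapse = ", ")))
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    coihap_error("coihap_config_error",
                 "cut_offset must lie within the recognition sequence")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme_spec")
}

#' ApoI restriction enzyme
#'
#' ApoI recognises `R^AATTY` (R = A/G, Y = C/T) and cuts after the first base
#' on the plus strand. It is the diagnostic enzyme of the COI PCR-RFLP assay
#' that discriminates *Bemisia tabaci* MED haplogroups.
#'
#' @return An `enzyme_spec` object.
#' @export
apoi <- function() restriction_enzyme("ApoI", "RAATTY", 1L)

#' @export
print.enzyme_spec <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("Restriction enzyme %s: %s (plus-strand cut)\n", x$name, site))
  invisible(x)
}
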