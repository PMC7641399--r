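#' Parse HLA allele names to two-field resolution
#'
#' HLA alleles are named `LOCUS*FF:FF[:FF[:FF]][G]`, e.g. `B*39:06:01`.
#' The first field identifies the serological group and the second the
#' protein; fields beyond the second distinguish synonymous or non-coding
#' variation and are dropped here, because population comparisons are
#' conventionally made at two-field (protein-level) resolution. A trailing
#' `G` (or `g`) marks a g-group: a set of alleles identical over the typed
#' exons that is reported under the name of its lowest-numbered member.
#'
#' @param x character vector of allele names.
#' @return A tibble with one row per input: `input`, `locus` (one of A, B,
#'   C, DRB1), `field1`, `field2` (two-digit strings), `g_group` (logical),
#'   `reduced` (`TRUE` when fields beyond the second were dropped), and
#'   `allele`, the canonical two-field name `LOCUS*FF:FF`.
#' @examples
#' parse_allele_name(c("A*02:01:01G", "B*39:06"))
#' @seealso [format_allele_name()], [reduce_to_two_field()]
#' @export
parse_allele_name <- function(x) {
  stopifnot(is.character(x))
  pat <- "^(A|B|C|DRB1)\\*(\\d{2,3}):(\\d{2,3})((?::\\d{2,3})*)([A-Za-z]?)$"
  m <- regmatches(x, regexec(pat, x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    abort(paste0(
      "Malformed HLA allele name(s): ",
      paste(shQuote(unique(x[bad])), collapse = ", "),
      ". Expected LOCUS*FF:FF[:FF...][G]."
    ))
  }
  m <- do.call(rbind, m)
  suffix <- m[, 6]
  bad_suffix <- !(suffix %in% c("", "G", "g", "N", "L", "S", "Q"))
  if (any(bad_suffix)) {
    abort(paste0(
      "Unrecognized allele-name suffix in: ",
      paste(shQuote(unique(x[bad_suffix])), collapse = ", ")
    ))
  }
  locus <- m[, 2]
  field1 <- m[, 3]
  field2 <- m[, 4]
  tibble::tibble(
    input = x,
    locus = locus,
    field1 = field1,
    field2 = field2,
    g_group = suffix %in% c("G", "g"),
    reduced = nzchar(m[, 5]),
    allele = paste0(locus, "*", field1, ":", field2)
  )
}

#' Format a parsed allele back to its two-field name
#'
#' @param parsed a tibble as returned by [parse_allele_name()], or a
#'   character vector of locus names when `field1`/`field2` are given.
#' @param field1,field2 optional character vectors of the two fields.
#' @return character vector of canonical two-field names.
#' @export
format_allele_name <- function(parsed, field1 = NULL, field2 = NULL) {
  if (is.character(parsed) && !is.null(field1)) {
    return(paste0(parsed, "*", field1, ":", field2))
  }
  paste0(parsed$locus, "*", parsed$field1, ":", parsed$field2)
}

#' Reduce allele names to canonical two-field resolution
#'
#' Idempotent: reducing an already two-field name returns it unchanged.
#' `NA` inputs (untyped) are passed through.
#'
#' @param x character vector of allele names at any resolution.
#' @return character vector of two-field names.
#' @export
reduce_to_two_field <- function(x) {
  out <- x
  ok <- !is.na(x)
  if (any(ok)) out[ok] <- parse_allele_name(x[ok])$allele
  out
}
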