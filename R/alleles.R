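#' @keywords internal
"_PACKAGE"

## Allele string handling ---------------------------------------------------
##
## Canonical form is LOCUS*FF:FF (two-field). Extra fields are truncated;
## the only expression-variant suffix accepted is N (null), and only at
## DRB3/4/5 where a null allele means "no expressed molecule".

DR_LOCI <- c("DRB1", "DRB3", "DRB4", "DRB5")
DRB345 <- c("DRB3", "DRB4", "DRB5")
DQ_LOCI <- c("DQA1", "DQB1")
ALL_LOCI <- c(DR_LOCI, DQ_LOCI)

#' Parse an HLA allele string
#'
#' Accepts one- or two-field allele strings such as `"DRB1*15"` or
#' `"DQB1*05:02"`. Fields beyond the second are truncated (protein-level
#' resolution); a trailing `N` marks a null allele.
#'
#' @param x character scalar allele string.
#' @param allowed character vector of permitted locus names.
#' @return list with `locus`, `value` (normalized string), `resolution`
#'   (`"two_field"` or `"low_res"`), and `null` (logical).
#' @keywords internal
parse_allele <- function(x, allowed = ALL_LOCI) {
  x0 <- x
  x <- toupper(trimws(x))
  if (!grepl("^[A-Z0-9]+\\*[0-9]{1,3}(:[0-9]{1,3}[A-Z]?)*$|^[A-Z0-9]+\\*[0-9]{1,3}[A-Z]$",
             x)) {
    stop("malformed allele string: '", x0, "'", call. = FALSE)
  }
  locus <- sub("\\*.*$", "", x)
  if (!locus %in% allowed) {
    stop("allele '", x0, "' has unsupported locus '", locus, "'",
         call. = FALSE)
  }
  rest <- sub("^[A-Z0-9]+\\*", "", x)
  fields <- strsplit(rest, ":", fixed = TRUE)[[1]]
  suffix <- sub("^[0-9]+", "", fields[length(fields)])
  fields <- sub("[A-Z]+$", "", fields)
  is_null <- FALSE
  if (nzchar(suffix)) {
    if (suffix != "N") {
      stop("expression-variant suffix '", suffix, "' in '", x0,
           "' is not supported (only N)", call. = FALSE)
    }
    is_null <- TRUE
  }
  fields <- fields[seq_len(min(2L, length(fields)))]
  fields <- sprintf("%02d", as.integer(fields))
  value <- paste0(locus, "*", paste(fields, collapse = ":"))
  resolution <- if (length(fields) >= 2L) "two_field" else "low_res"
  list(locus = locus, value = value, resolution = resolution, null = is_null)
}

#' Normalize an allele string to canonical two-field form
#' @param x character vector of allele strings.
#' @param allowed permitted loci.
#' @return character vector of normalized strings.
#' @export
normalize_allele <- function(x, allowed = ALL_LOCI) {
  vapply(x, function(a) parse_allele(a, allowed)$value, character(1),
         USE.NAMES = FALSE)
}

## first antigen-group field, e.g. "DRB1*15:01" -> "15"
allele_first_field <- function(x) {
  sub("^[A-Z0-9]+\\*([0-9]+).*$", "\\1", x)
}

allele_locus <- function(x) sub("\\*.*$", "", x)
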