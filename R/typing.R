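## Subject typing -----------------------------------------------------------
##
## A subject's HLA typing occupies eight slots: DRB1_1/2, DRB345_1/2,
## DQA1_1/2, DQB1_1/2. The two DRB345 slots jointly hold the subject's
## DRB3/DRB4/DRB5 alleles; a blank slot is a null (no expressed secondary
## DR beta chain). After imputation, slot index encodes haplotype phase:
## slot 1 of every locus comes from haplotype 1.

TYPING_SLOTS <- c("DRB1_1", "DRB1_2", "DRB345_1", "DRB345_2",
                  "DQA1_1", "DQA1_2", "DQB1_1", "DQB1_2")

#' Construct a subject typing
#'
#' @param subject_id subject identifier.
#' @param role `"donor"` or `"recipient"`.
#' @param pair_id donor-recipient pair identifier.
#' @param ethnicity population label (may be `NA`).
#' @param alleles named character vector or list over the slots
#'   `DRB1_1, DRB1_2, DRB345_1, DRB345_2, DQA1_1, DQA1_2, DQB1_1, DQB1_2`;
#'   `NA`/`""` in a DRB345 slot means a null slot, elsewhere an absent
#'   (to-be-imputed) call.
#' @return object of class `subject_typing` with a `calls` data.frame
#'   (`slot`, `locus`, `value`, `resolution`).
#' @export
subject_typing <- function(subject_id, role, pair_id = NA_character_,
                           ethnicity = NA_character_, alleles) {
  role <- match.arg(role, c("donor", "recipient"))
  if (!all(TYPING_SLOTS %in% names(alleles))) {
    stop("alleles must be named over all eight typing slots", call. = FALSE)
  }
  calls <- lapply(TYPING_SLOTS, function(sl) {
    v <- alleles[[sl]]
    blank <- is.null(v) || is.na(v) || !nzchar(trimws(v))
    drb345 <- grepl("^DRB345", sl)
    if (blank) {
      return(data.frame(slot = sl, locus = NA_character_, value = NA_character_,
                        resolution = if (drb345) "null" else "absent",
                        stringsAsFactors = FALSE))
    }
    allowed <- if (drb345) DRB345 else sub("_[12]$", "", sl)
    p <- parse_allele(v, allowed = allowed)
    if (p$null) {
      if (!drb345) {
        stop("null allele outside DRB3/4/5 is not supported: ", v,
             call. = FALSE)
      }
      return(data.frame(slot = sl, locus = NA_character_, value = NA_character_,
                        resolution = "null", stringsAsFactors = FALSE))
    }
    data.frame(slot = sl, locus = p$locus, value = p$value,
               resolution = p$resolution, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  st <- structure(list(subject_id = as.character(subject_id), role = role,
                       pair_id = as.character(pair_id),
                       ethnicity = as.character(ethnicity), calls = calls),
                  class = "subject_typing")
  validate_subject_typing(st)
  st
}

#' Validate subject-typing invariants
#' @param st a `subject_typing`.
#' @return `st` invisibly; errors on violation.
#' @export
validate_subject_typing <- function(st) {
  stopifnot(inherits(st, "subject_typing"))
  calls <- st$calls
  stopifnot(identical(calls$slot, TYPING_SLOTS))
  drb345 <- calls[grepl("^DRB345", calls$slot), ]
  n_named <- sum(drb345$locus %in% DRB345, na.rm = TRUE)
  n_null <- sum(drb345$resolution == "null")
  if (n_named + n_null != 2L) {
    stop("subject ", st$subject_id,
         ": DRB3/4/5 slots must sum to exactly 2 (named + null)",
         call. = FALSE)
  }
  for (loc in c("DRB1", "DQA1", "DQB1")) {
    n <- sum(grepl(paste0("^", loc, "_"), calls$slot))
    if (n != 2L) stop("subject ", st$subject_id, ": expected 2 ", loc,
                      " slots", call. = FALSE)
  }
  invisible(st)
}

#' Is a typing fully resolved to two-field alleles?
#' @param st a `subject_typing`.
#' @return logical scalar; null DRB345 slots are considered resolved.
#' @export
is_two_field <- function(st) {
  all(st$calls$resolution %in% c("two_field", "null"))
}

#' Parse a typing table (CSV) into subject typings
#'
#' Expected columns: `subject_id`, `role`, `pair_id`, `ethnicity`, and the
#' eight slot columns `DRB1_1 ... DQB1_2`. A blank `DRB345_*` cell is a
#' null slot; a blank cell at other loci is an absent call flagged for
#' imputation.
#'
#' @param path CSV file path, or a data.frame in that layout.
#' @return list of `subject_typing`.
#' @export
parse_typing_table <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("typing file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  need <- c("subject_id", "role", TYPING_SLOTS)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("typing table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"pair_id" %in% names(df)) df$pair_id <- NA_character_
  if (!"ethnicity" %in% names(df)) df$ethnicity <- NA_character_
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      subject_typing(row$subject_id, row$role, row$pair_id, row$ethnicity,
                     as.list(row[TYPING_SLOTS])),
      error = function(e) stop("typing row ", i, " (", row$subject_id, "): ",
                               conditionMessage(e), call. = FALSE))
  })
}

#' Write subject typings to the CSV slot layout
#' @param typings list of `subject_typing`.
#' @param path output CSV path; `NULL` returns the data.frame.
#' @return the data.frame, invisibly when written.
#' @export
write_typing_table <- function(typings, path = NULL) {
  rows <- lapply(typings, function(st) {
    v <- stats::setNames(st$calls$value, st$calls$slot)
    v[is.na(v)] <- ""
    blank_na <- function(x) if (is.na(x)) "" else x
    c(subject_id = st$subject_id, role = st$role,
      pair_id = blank_na(st$pair_id), ethnicity = blank_na(st$ethnicity), v)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @export
print.subject_typing <- function(x, ...) {
  cat("<subject_typing>", x$subject_id, paste0("(", x$role, ")"),
      if (!is.na(x$ethnicity)) x$ethnicity else "", "\n")
  v <- ifelse(is.na(x$calls$value), paste0("<", x$calls$resolution, ">"),
              x$calls$value)
  cat(paste0("  ", format(x$calls$slot), "  ", v, collapse = "\n"), "\n")
  invisible(x)
}
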