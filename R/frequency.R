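## Population haplotype-frequency tables ------------------------------------
##
## One row per (population, haplotype); a haplotype is the ordered allele
## string DRB1 ~ DRB345 ~ DQA1 ~ DQB1, with an empty DRB345 field for a
## null slot. Used to complete low-resolution or absent calls to two-field
## alleles via a most-likely-haplotype-pair assignment.

HAP_LOCI <- c("DRB1", "DRB345", "DQA1", "DQB1")

#' Construct a haplotype-frequency table
#' @param df data.frame with columns `population`, `DRB1`, `DRB345`,
#'   `DQA1`, `DQB1`, `frequency`. `DRB345 = ""` encodes a null slot.
#' @return object of class `haplotype_freq_table` (a validated data.frame).
#' @export
haplotype_freq_table <- function(df) {
  need <- c("population", HAP_LOCI, "frequency")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("frequency table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  df$frequency <- as.numeric(df$frequency)
  if (any(is.na(df$frequency)) || any(df$frequency < 0)) {
    stop("frequencies must be non-negative numbers", call. = FALSE)
  }
  df$DRB1 <- normalize_allele(df$DRB1, allowed = "DRB1")
  df$DQA1 <- normalize_allele(df$DQA1, allowed = "DQA1")
  df$DQB1 <- normalize_allele(df$DQB1, allowed = "DQB1")
  d345 <- trimws(as.character(df$DRB345))
  d345[is.na(df$DRB345)] <- ""
  nz <- nzchar(d345)
  d345[nz] <- normalize_allele(d345[nz], allowed = DRB345)
  df$DRB345 <- d345
  sums <- tapply(df$frequency, df$population, sum)
  if (any(sums > 1 + 1e-6)) {
    stop("frequencies exceed 1 for population(s): ",
         paste(names(sums)[sums > 1 + 1e-6], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("haplotype_freq_table", "data.frame"))
}

#' Load a haplotype-frequency table from CSV
#' @param path CSV with columns population, DRB1, DRB345, DQA1, DQB1,
#'   frequency.
#' @return a `haplotype_freq_table`.
#' @export
load_frequency_table <- function(path) {
  if (!file.exists(path)) stop("frequency file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frequency = "numeric"))
  df$DRB345[is.na(df$DRB345)] <- ""
  haplotype_freq_table(df)
}

#' Write a haplotype-frequency table to CSV
#' @param tab a `haplotype_freq_table`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_frequency_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

hap_string <- function(tab) {
  paste(tab$DRB1, tab$DRB345, tab$DQA1, tab$DQB1, sep = "~")
}

## rows for one population; pooled (frequency-summed across populations,
## renormalized) when the label is absent from the table
population_rows <- function(tab, population) {
  rows <- tab[tab$population == population, , drop = FALSE]
  if (!nrow(rows)) {
    key <- hap_string(tab)
    agg <- stats::aggregate(list(frequency = tab$frequency), by = list(key = key),
                            FUN = sum)
    first <- tab[!duplicated(key), c(HAP_LOCI)]
    first$key <- key[!duplicated(key)]
    rows <- merge(first, agg, by = "key")
    rows$population <- "pooled"
    rows$frequency <- rows$frequency / sum(rows$frequency)
    rows <- rows[, c("population", HAP_LOCI, "frequency")]
  }
  rows[order(hap_string(rows)), , drop = FALSE]
}
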