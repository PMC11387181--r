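## Two-field imputation ------------------------------------------------------
##
## Low-resolution and absent calls are completed to two-field alleles by
## choosing, among all haplotype pairs in the population's frequency table
## compatible with the observed calls, the pair maximizing the product of
## the two haplotype frequencies (most-likely single assignment). Ties are
## broken by lexicographic order of the concatenated haplotype strings so
## the result is deterministic across runs and platforms. Compatibility is
## assessed per locus (observed typings are unphased); the returned typing
## is haplotype-ordered, which fixes the DQ alpha1-beta1 pairing phase.

## can observed call (value,resolution) be satisfied by haplotype allele a?
## a == "" encodes a null DRB345 slot.
call_compatible <- function(value, resolution, a) {
  switch(resolution,
    two_field = nzchar(a) && a == value,
    low_res = nzchar(a) && allele_locus(a) == allele_locus(value) &&
      allele_first_field(a) == allele_first_field(value),
    null = !nzchar(a),
    absent = TRUE,
    stop("unknown resolution: ", resolution))
}

#' Impute two-field alleles from a haplotype-frequency table
#'
#' @param typing a `subject_typing` (possibly with low-resolution, absent,
#'   or null calls).
#' @param freq a `haplotype_freq_table`.
#' @param population population label; when absent from the table, a pooled
#'   table (frequency-summed across populations) is used.
#' @return a fully two-field `subject_typing`, slots ordered by haplotype
#'   (slot 1 = lexicographically smaller haplotype of the chosen pair).
#'   Already fully-resolved typings are returned unchanged.
#' @export
impute_two_field <- function(typing, freq,
                             population = typing$ethnicity) {
  stopifnot(inherits(typing, "subject_typing"))
  if (is_two_field(typing)) return(typing)
  if (is.null(population) || is.na(population)) population <- "<pooled>"
  rows <- population_rows(freq, population)
  H <- nrow(rows)
  if (!H) stop("empty frequency table", call. = FALSE)
  hs <- hap_string(rows)

  calls <- typing$calls
  ## compat[k, h]: call k satisfiable by haplotype h at the call's locus
  loc_of_slot <- c(DRB1_1 = "DRB1", DRB1_2 = "DRB1",
                   DRB345_1 = "DRB345", DRB345_2 = "DRB345",
                   DQA1_1 = "DQA1", DQA1_2 = "DQA1",
                   DQB1_1 = "DQB1", DQB1_2 = "DQB1")
  compat <- matrix(FALSE, nrow = 8L, ncol = H, dimnames = list(calls$slot))
  for (k in seq_len(8L)) {
    hap_alleles <- rows[[loc_of_slot[calls$slot[k]]]]
    compat[k, ] <- vapply(hap_alleles, function(a)
      call_compatible(calls$value[k], calls$resolution[k], a), logical(1))
  }

  ## per locus group (slots a,b) a pair (i,j) is compatible if either
  ## assignment of the two unphased calls to the two haplotypes works
  groups <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L))
  best <- NULL
  for (i in seq_len(H)) {
    for (j in i:H) {
      ok <- TRUE
      for (g in groups) {
        a <- g[1]; b <- g[2]
        if (!((compat[a, i] && compat[b, j]) ||
              (compat[a, j] && compat[b, i]))) { ok <- FALSE; break }
      }
      if (!ok) next
      score <- rows$frequency[i] * rows$frequency[j]
      key <- paste(hs[i], hs[j], sep = "|")   # hs sorted, so i<=j => ordered
      if (is.null(best) || score > best$score ||
          (score == best$score && key < best$key)) {
        best <- list(i = i, j = j, score = score, key = key)
      }
    }
  }
  if (is.null(best)) {
    unresolved <- calls$slot[!calls$resolution %in% c("two_field", "null")]
    stop("no compatible haplotype pair for subject ", typing$subject_id,
         " (population ", population, "); unresolved call(s): ",
         paste(ifelse(is.na(calls$value), calls$slot, calls$value),
               collapse = ", "), call. = FALSE)
  }
  h1 <- rows[best$i, ]; h2 <- rows[best$j, ]
  alleles <- c(DRB1_1 = h1$DRB1, DRB1_2 = h2$DRB1,
               DRB345_1 = h1$DRB345, DRB345_2 = h2$DRB345,
               DQA1_1 = h1$DQA1, DQA1_2 = h2$DQA1,
               DQB1_1 = h1$DQB1, DQB1_2 = h2$DQB1)
  subject_typing(typing$subject_id, typing$role, typing$pair_id,
                 typing$ethnicity, as.list(alleles))
}
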