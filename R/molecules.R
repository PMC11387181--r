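## Molecule enumeration ------------------------------------------------------
##
## The scorable units are expressed HLA molecules: one per DR beta chain
## (DRB1 always, DRB3/4/5 when the slot is not null) and one DQ
## alpha1-beta1 heterodimer per inherited haplotype (slot index = phase).
## Homozygous subjects contribute two identical molecules; null DRB345
## slots contribute none.

#' Enumerate scorable molecules for a fully typed subject
#'
#' @param typing a fully two-field `subject_typing`.
#' @param registry an `eplet_registry`.
#' @return data.frame with columns `molecule_id`, `kind`
#'   (`"DR_beta"`/`"DQ_heterodimer"`), `locus_class` (`"DR"`/`"DQ"`),
#'   `alleles` (list column), `eplets` (list column: union over the
#'   molecule's constituent alleles).
#' @export
enumerate_molecules <- function(typing, registry) {
  stopifnot(inherits(typing, "subject_typing"),
            inherits(registry, "eplet_registry"))
  if (!is_two_field(typing)) {
    stop("typing for ", typing$subject_id,
         " is not fully two-field; impute first", call. = FALSE)
  }
  calls <- typing$calls
  val <- stats::setNames(calls$value, calls$slot)
  out <- list()
  add <- function(kind, alleles, idx) {
    eps <- unique(unlist(lapply(alleles, eplets_for_allele, reg = registry),
                         use.names = FALSE))
    if (is.null(eps)) eps <- character()
    out[[length(out) + 1L]] <<- list(
      molecule_id = paste(typing$subject_id, kind, idx, sep = ":"),
      kind = kind,
      locus_class = if (kind == "DR_beta") "DR" else "DQ",
      alleles = alleles, eplets = eps)
  }
  k <- 0L
  for (sl in c("DRB1_1", "DRB1_2", "DRB345_1", "DRB345_2")) {
    a <- val[[sl]]
    if (is.na(a)) next                       # null DRB345 slot
    k <- k + 1L
    add("DR_beta", a, k)
  }
  for (s in 1:2) {
    add("DQ_heterodimer",
        c(val[[paste0("DQA1_", s)]], val[[paste0("DQB1_", s)]]), s)
  }
  data.frame(
    molecule_id = vapply(out, `[[`, character(1), "molecule_id"),
    kind = vapply(out, `[[`, character(1), "kind"),
    locus_class = vapply(out, `[[`, character(1), "locus_class"),
    alleles = I(lapply(out, `[[`, "alleles")),
    eplets = I(lapply(out, `[[`, "eplets")),
    stringsAsFactors = FALSE)
}
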