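## Molecule-level eplet mismatch --------------------------------------------
##
## A donor molecule's mismatched eplets are those present on the donor
## molecule but absent from every recipient molecule of the same locus
## class: set difference of the donor eplet set against the union of the
## recipient repertoire. The recipient-level score at each class is the
## maximum over donor molecules ("single-molecule maximum").

#' Eplet mismatch of one donor molecule against the recipient repertoire
#'
#' @param donor_mol one row of [enumerate_molecules()] output (data.frame
#'   of one row, or a list with `molecule_id`, `locus_class`, `eplets`).
#' @param recipient_mols [enumerate_molecules()] output for the recipient,
#'   restricted to (or at least containing only) molecules of the donor
#'   molecule's locus class.
#' @param registry an `eplet_registry` (used for contract checks).
#' @return list of class `molecule_mismatch`: `molecule_id`,
#'   `mismatched_eplets` (character vector), `count`.
#' @export
molecule_eplet_mismatch <- function(donor_mol, recipient_mols, registry) {
  if (is.data.frame(donor_mol)) {
    stopifnot(nrow(donor_mol) == 1L)
    donor_mol <- list(molecule_id = donor_mol$molecule_id,
                      locus_class = donor_mol$locus_class,
                      eplets = donor_mol$eplets[[1]])
  }
  if (nrow(recipient_mols) &&
      any(recipient_mols$locus_class != donor_mol$locus_class)) {
    stop("locus-class mixing: donor ", donor_mol$locus_class,
         " molecule compared against recipient ",
         paste(unique(recipient_mols$locus_class), collapse = "/"),
         " molecule(s)", call. = FALSE)
  }
  rec_union <- unique(unlist(recipient_mols$eplets, use.names = FALSE))
  mm <- setdiff(donor_mol$eplets, rec_union)
  structure(list(molecule_id = donor_mol$molecule_id,
                 mismatched_eplets = mm, count = length(mm)),
            class = "molecule_mismatch")
}

#' Recipient-level mismatch summary for one donor-recipient pair
#'
#' Scores every donor molecule against the recipient's same-class
#' repertoire and records the per-class single-molecule maxima and
#' antigen-level mismatch counts.
#'
#' @param donor,recipient fully two-field `subject_typing` objects.
#' @param registry an `eplet_registry`.
#' @return list of class `mismatch_summary`: `pair_id`, `molecules`
#'   (data.frame `molecule_id`, `kind`, `locus_class`, `count`,
#'   `mismatched` list column, `alleles` list column), `dr_max`, `dq_max`,
#'   `dr_antigen_mm`, `dq_antigen_mm`.
#' @export
recipient_mismatch_summary <- function(donor, recipient, registry) {
  dmols <- enumerate_molecules(donor, registry)
  rmols <- enumerate_molecules(recipient, registry)
  res <- lapply(seq_len(nrow(dmols)), function(i) {
    cls <- dmols$locus_class[i]
    molecule_eplet_mismatch(dmols[i, ], rmols[rmols$locus_class == cls, ],
                            registry)
  })
  counts <- vapply(res, `[[`, integer(1), "count")
  mol <- data.frame(molecule_id = dmols$molecule_id, kind = dmols$kind,
                    locus_class = dmols$locus_class, count = counts,
                    stringsAsFactors = FALSE)
  mol$mismatched <- I(lapply(res, `[[`, "mismatched_eplets"))
  mol$alleles <- dmols$alleles
  max0 <- function(x) if (length(x)) max(x) else 0L
  structure(list(
    pair_id = donor$pair_id,
    molecules = mol,
    dr_max = max0(counts[dmols$locus_class == "DR"]),
    dq_max = max0(counts[dmols$locus_class == "DQ"]),
    dr_antigen_mm = antigen_mismatch(donor, recipient, "DRB1"),
    dq_antigen_mm = antigen_mismatch(donor, recipient, "DQB1")),
    class = "mismatch_summary")
}

#' Antigen-level (first-field) mismatch count at a locus
#'
#' Number of donor first-field antigen groups at the locus absent from the
#' recipient's first-field groups (0, 1, or 2).
#'
#' @param donor,recipient `subject_typing` objects typed at the locus.
#' @param locus `"DRB1"` or `"DQB1"`.
#' @return integer in 0..2.
#' @export
antigen_mismatch <- function(donor, recipient, locus = c("DRB1", "DQB1")) {
  locus <- match.arg(locus)
  grp <- function(st) {
    v <- st$calls$value[grepl(paste0("^", locus, "_"), st$calls$slot)]
    if (anyNA(v)) stop("missing ", locus, " typing for ", st$subject_id,
                       call. = FALSE)
    unique(allele_first_field(v))
  }
  length(setdiff(grp(donor), grp(recipient)))
}

#' Attribute a DSA specificity to donor molecules
#'
#' Matches an antibody specificity string against the donor's molecule
#' alleles: two-field strings match exactly, one-field strings by
#' first-field prefix, and serologic labels such as `"DR17"`/`"DQ5"` are
#' (optionally) resolved by the first-field prefix rule against DRB1/DQB1.
#' An empty result means the antibody is not donor-directed at DR/DQ.
#'
#' @param dsa_specificity specificity string (e.g. `"DQB1*05:02"`,
#'   `"DRB1*04"`, `"DR4"`).
#' @param donor_mols [enumerate_molecules()] output for the donor.
#' @param serologic how to treat serologic labels: `"prefix"` resolves
#'   `DRn`/`DQn` to a first-field prefix on DRB1/DQB1; `"reject"` errors.
#' @return character vector of matching molecule ids (possibly empty; a
#'   warning is issued for out-of-class specificities such as HLA Class I).
#' @export
attribute_dsa_to_molecules <- function(dsa_specificity, donor_mols,
                                       serologic = c("prefix", "reject")) {
  serologic <- match.arg(serologic)
  s <- toupper(trimws(dsa_specificity))
  if (!nzchar(s)) stop("empty DSA specificity", call. = FALSE)
  match_fun <- NULL
  if (grepl("\\*", s)) {
    locus <- sub("\\*.*$", "", s)
    if (!locus %in% ALL_LOCI) {
      warning("specificity '", s, "' is outside HLA-DR/DQ; not attributed")
      return(character())
    }
    p <- parse_allele(s, allowed = ALL_LOCI)
    if (p$resolution == "two_field") {
      match_fun <- function(a) a == p$value
    } else {
      ff <- allele_first_field(p$value)
      match_fun <- function(a) allele_locus(a) == locus &&
        allele_first_field(a) == ff
    }
  } else if (grepl("^(DR|DQ)[0-9]{1,2}$", s)) {
    if (serologic == "reject") {
      stop("serologic specificity '", s, "' rejected by configuration",
           call. = FALSE)
    }
    locus <- if (startsWith(s, "DR")) "DRB1" else "DQB1"
    ff <- sprintf("%02d", as.integer(sub("^(DR|DQ)", "", s)))
    match_fun <- function(a) allele_locus(a) == locus &&
      allele_first_field(a) == ff
  } else if (grepl("^(A|B|C|CW|DP)[0-9*]", s)) {
    warning("specificity '", s, "' is outside HLA-DR/DQ; not attributed")
    return(character())
  } else {
    stop("unparseable DSA specificity: '", dsa_specificity, "'",
         call. = FALSE)
  }
  hit <- vapply(donor_mols$alleles, function(al) any(vapply(al, match_fun,
                                                            logical(1))),
                logical(1))
  donor_mols$molecule_id[hit]
}
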