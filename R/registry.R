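## Eplet registry -----------------------------------------------------------
##
## The registry maps two-field alleles to sets of eplet identifiers. Eplets
## are small patches of polymorphic surface-exposed residues; their
## structural derivation is registry provenance, not recomputed here. The
## catalog records for each eplet its locus class (DR or DQ) and chain
## (alpha/beta): DR eplets are always beta-chain (DRB1/3/4/5 beta chains),
## DQ eplets are alpha-chain iff they are carried by DQA1 alleles.

#' Construct an eplet registry
#'
#' @param allele_to_eplets named list: two-field allele string -> character
#'   vector of eplet ids (possibly empty).
#' @param eplets data.frame with columns `id`, `locus_class` ("DR"/"DQ"),
#'   `chain` ("alpha"/"beta"), and optionally `name`. If `NULL` the catalog
#'   is inferred from the allele map.
#' @return object of class `eplet_registry`.
#' @export
eplet_registry <- function(allele_to_eplets, eplets = NULL) {
  alleles <- names(allele_to_eplets)
  norm <- normalize_allele(alleles)
  if (anyDuplicated(norm)) {
    stop("duplicate allele after normalization: ",
         paste(norm[duplicated(norm)], collapse = ", "), call. = FALSE)
  }
  names(allele_to_eplets) <- norm
  allele_to_eplets <- lapply(allele_to_eplets, function(e) {
    e <- unique(as.character(e))
    e[nzchar(e)]
  })
  if (is.null(eplets)) {
    eplets <- infer_eplet_catalog(allele_to_eplets)
  }
  stopifnot(all(c("id", "locus_class", "chain") %in% names(eplets)))
  if (!"name" %in% names(eplets)) eplets$name <- eplets$id
  if (anyDuplicated(eplets$id)) {
    stop("duplicate eplet ids in catalog", call. = FALSE)
  }
  reg <- structure(list(allele_to_eplets = allele_to_eplets,
                        eplets = eplets[, c("id", "locus_class", "chain", "name")]),
                   class = "eplet_registry")
  validate_eplet_registry(reg)
  reg
}

infer_eplet_catalog <- function(allele_to_eplets) {
  loci <- allele_locus(names(allele_to_eplets))
  rows <- list()
  for (i in seq_along(allele_to_eplets)) {
    ids <- allele_to_eplets[[i]]
    if (!length(ids)) next
    cls <- if (loci[i] %in% DR_LOCI) "DR" else "DQ"
    chain <- if (loci[i] == "DQA1") "alpha" else "beta"
    rows[[length(rows) + 1L]] <- data.frame(id = ids, locus_class = cls,
                                            chain = chain,
                                            stringsAsFactors = FALSE)
  }
  cat <- unique(do.call(rbind, c(rows, list(
    data.frame(id = character(), locus_class = character(),
               chain = character())))))
  if (anyDuplicated(cat$id)) {
    bad <- unique(cat$id[duplicated(cat$id)])
    stop("eplet id(s) assigned to conflicting locus class/chain: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cat$name <- cat$id
  rownames(cat) <- NULL
  cat
}

#' Validate eplet registry invariants
#' @param reg an `eplet_registry`.
#' @return `reg`, invisibly; errors on violation.
#' @export
validate_eplet_registry <- function(reg) {
  stopifnot(inherits(reg, "eplet_registry"))
  cat <- reg$eplets
  if (!all(cat$locus_class %in% c("DR", "DQ")) ||
      !all(cat$chain %in% c("alpha", "beta"))) {
    stop("invalid locus_class/chain in eplet catalog", call. = FALSE)
  }
  if (any(cat$locus_class == "DR" & cat$chain != "beta")) {
    stop("DR eplets must be beta-chain", call. = FALSE)
  }
  cls <- stats::setNames(cat$locus_class, cat$id)
  chn <- stats::setNames(cat$chain, cat$id)
  for (al in names(reg$allele_to_eplets)) {
    ids <- reg$allele_to_eplets[[al]]
    unknown <- setdiff(ids, cat$id)
    if (length(unknown)) {
      stop("allele ", al, " references unknown eplet(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    locus <- allele_locus(al)
    want_cls <- if (locus %in% DR_LOCI) "DR" else "DQ"
    if (any(cls[ids] != want_cls)) {
      stop("allele ", al, " mapped to ", cls[ids][cls[ids] != want_cls][1],
           "-class eplet(s); expected ", want_cls, call. = FALSE)
    }
    if (locus == "DQA1" && any(chn[ids] != "alpha")) {
      stop("DQA1 allele ", al, " mapped to beta-chain eplet(s)", call. = FALSE)
    }
    if (locus == "DQB1" && any(chn[ids] != "beta")) {
      stop("DQB1 allele ", al, " mapped to alpha-chain eplet(s)", call. = FALSE)
    }
  }
  invisible(reg)
}

#' Eplet set for a two-field allele
#' @param reg an `eplet_registry`.
#' @param allele two-field allele string.
#' @return character vector of eplet ids.
#' @export
eplets_for_allele <- function(reg, allele) {
  e <- reg$allele_to_eplets[[allele]]
  if (is.null(e)) {
    stop("allele not in registry: ", allele, call. = FALSE)
  }
  e
}

#' Load an eplet registry from TSV
#'
#' Expected columns: `allele`, `locus_class`, `eplets` (semicolon-separated
#' eplet ids; empty for an allele with no assigned eplets).
#'
#' @param path file path.
#' @return an `eplet_registry`.
#' @export
load_eplet_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("allele", "eplets")
  if (!all(need %in% names(df))) {
    stop("registry file must have columns 'allele' and 'eplets'",
         call. = FALSE)
  }
  sets <- lapply(df$eplets, function(s) {
    ids <- strsplit(s, ";", fixed = TRUE)[[1]]
    trimws(ids[nzchar(trimws(ids))])
  })
  alleles <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(normalize_allele(df$allele[i]),
             error = function(e) stop("registry row ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, character(1))
  names(sets) <- alleles
  cat <- NULL
  if ("locus_class" %in% names(df)) {
    ## cross-check declared class against allele locus
    locus <- allele_locus(alleles)
    want <- ifelse(locus %in% DR_LOCI, "DR", "DQ")
    bad <- which(toupper(df$locus_class) != want)
    if (length(bad)) {
      stop("registry row ", bad[1], ": allele ", alleles[bad[1]],
           " declared ", df$locus_class[bad[1]], "-class but locus is ",
           want[bad[1]], call. = FALSE)
    }
  }
  eplet_registry(sets, eplets = cat)
}

#' Write an eplet registry to TSV (round-trips with [load_eplet_registry()])
#' @param reg an `eplet_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eplet_registry <- function(reg, path) {
  alleles <- names(reg$allele_to_eplets)
  locus <- allele_locus(alleles)
  df <- data.frame(
    allele = alleles,
    locus_class = ifelse(locus %in% DR_LOCI, "DR", "DQ"),
    eplets = vapply(reg$allele_to_eplets, paste, character(1),
                    collapse = ";"),
    stringsAsFactors = FALSE)
  df <- df[order(df$allele), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.eplet_registry <- function(x, ...) {
  cat("<eplet_registry>", length(x$allele_to_eplets), "alleles,",
      nrow(x$eplets), "eplets (",
      sum(x$eplets$locus_class == "DR"), "DR /",
      sum(x$eplets$locus_class == "DQ"), "DQ )\n")
  invisible(x)
}
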