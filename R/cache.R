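## Haplotype-pair mismatch cache --------------------------------------------
##
## For cohort simulation and large-scale recovery experiments the
## single-molecule maxima depend only on the donor's and recipient's
## unordered haplotype pairs, so they are precomputed once per
## (registry, frequency-table) with incidence-matrix algebra. The cache
## is an optimization of the mismatch engine, not a second definition:
## equality with recipient_mismatch_summary() is asserted in the test
## suite over random pairings.

#' Precompute single-molecule maxima over all haplotype-pair combinations
#'
#' @param registry an `eplet_registry`.
#' @param freq_table a `haplotype_freq_table` (its distinct haplotypes
#'   define the genotype space).
#' @return object of class `mismatch_cache`: `haps` (data.frame of
#'   distinct haplotypes), `pair_index` (HxH symmetric matrix of combo
#'   ids), `dr_max`/`dq_max` (combo x combo integer matrices, donor combo
#'   in rows, recipient combo in columns), `arg_dr`/`arg_dq` (allele string of a molecule
#'   attaining the maximum, for DSA specificity emission).
#' @export
build_mismatch_cache <- function(registry, freq_table) {
  key <- hap_string(freq_table)
  haps <- as.data.frame(freq_table)[!duplicated(key), HAP_LOCI]
  haps <- haps[order(hap_string(haps)), , drop = FALSE]
  rownames(haps) <- NULL
  H <- nrow(haps)

  cat <- registry$eplets
  dr_ids <- cat$id[cat$locus_class == "DR"]
  dq_ids <- cat$id[cat$locus_class == "DQ"]
  inc <- function(allele, ids) as.numeric(ids %in%
                                            eplets_for_allele(registry, allele))

  ## DR molecules: one per DRB1, one per expressed DRB345
  mol_hap <- integer(0); mol_allele <- character(0)
  cols <- list()
  for (h in seq_len(H)) {
    for (a in c(haps$DRB1[h], haps$DRB345[h])) {
      if (!nzchar(a)) next
      cols[[length(cols) + 1L]] <- inc(a, dr_ids)
      mol_hap <- c(mol_hap, h); mol_allele <- c(mol_allele, a)
    }
  }
  M_dr <- do.call(cbind, cols)                     # |E_dr| x n_mol
  M_dq <- vapply(seq_len(H), function(h)           # |E_dq| x H
    pmin(1, inc(haps$DQA1[h], dq_ids) + inc(haps$DQB1[h], dq_ids)),
    numeric(length(dq_ids)))

  combos <- which(upper.tri(diag(H), diag = TRUE), arr.ind = TRUE)
  combos <- combos[order(combos[, 1], combos[, 2]), , drop = FALSE]
  nC <- nrow(combos)
  pair_index <- matrix(NA_integer_, H, H)
  for (c0 in seq_len(nC)) {
    i <- combos[c0, 1]; j <- combos[c0, 2]
    pair_index[i, j] <- c0; pair_index[j, i] <- c0
  }

  ## recipient repertoire unions per combo
  U_dr <- vapply(seq_len(nC), function(c0) {
    sel <- mol_hap %in% combos[c0, ]
    pmin(1, rowSums(M_dr[, sel, drop = FALSE]))
  }, numeric(length(dr_ids)))
  U_dq <- vapply(seq_len(nC), function(c0)
    pmin(1, M_dq[, combos[c0, 1]] + M_dq[, combos[c0, 2]]),
    numeric(length(dq_ids)))

  C_dr <- crossprod(M_dr, 1 - U_dr)                # n_mol x nC counts
  C_dq <- crossprod(M_dq, 1 - U_dq)                # H x nC counts

  dr_max <- matrix(0L, nC, nC); dq_max <- matrix(0L, nC, nC)
  arg_dr <- matrix(NA_character_, nC, nC); arg_dq <- matrix(NA_character_,
                                                            nC, nC)
  for (c0 in seq_len(nC)) {
    mols <- which(mol_hap %in% combos[c0, ])
    block <- C_dr[mols, , drop = FALSE]
    best <- max.col(t(block), ties.method = "first")
    dr_max[c0, ] <- as.integer(round(block[cbind(best, seq_len(nC))]))
    arg_dr[c0, ] <- mol_allele[mols[best]]
    i <- combos[c0, 1]; j <- combos[c0, 2]
    ci <- C_dq[i, ]; cj <- C_dq[j, ]
    use_i <- ci >= cj
    dq_max[c0, ] <- as.integer(round(ifelse(use_i, ci, cj)))
    arg_dq[c0, ] <- ifelse(use_i, haps$DQB1[i], haps$DQB1[j])
  }
  structure(list(haps = haps, pair_index = pair_index,
                 dr_max = dr_max, dq_max = dq_max,
                 arg_dr = arg_dr, arg_dq = arg_dq),
            class = "mismatch_cache")
}

## typing-slot values for haplotype pair (i, j) of a cache
cache_typing_alleles <- function(cache, i, j) {
  h1 <- cache$haps[i, ]; h2 <- cache$haps[j, ]
  list(DRB1_1 = h1$DRB1, DRB1_2 = h2$DRB1,
       DRB345_1 = h1$DRB345, DRB345_2 = h2$DRB345,
       DQA1_1 = h1$DQA1, DQA1_2 = h2$DQA1,
       DQB1_1 = h1$DQB1, DQB1_2 = h2$DQB1)
}
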