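## Synthetic eplet registries and frequency tables --------------------------
##
## The fixture registry is built so the packaged scales hold by
## construction: every DR-class allele carries a common DR core, so any
## DR molecule mismatch is a subset of the 21-eplet DR variable pool
## (range 0-21); DQ alpha and beta alleles carry locus cores plus variable
## pools of 12 (alpha) and 20 (beta), capping DQ molecule mismatch at 32.
## Each locus includes one minimal (core-only) and one maximal (full
## variable pool) allele, so the extremes of both ranges are achievable.

DRB1_POOL <- c("DRB1*01:01", "DRB1*03:01", "DRB1*04:05", "DRB1*07:01",
               "DRB1*08:03", "DRB1*09:01", "DRB1*11:01", "DRB1*12:02",
               "DRB1*15:01", "DRB1*15:02", "DRB1*16:02", "DRB1*10:01")
DRB3_POOL <- c("DRB3*01:01", "DRB3*02:02", "DRB3*03:01")
DRB4_POOL <- c("DRB4*01:01", "DRB4*01:03")
DRB5_POOL <- c("DRB5*01:01", "DRB5*01:02", "DRB5*02:02")
DQA1_POOL <- c("DQA1*01:02", "DQA1*01:03", "DQA1*02:01", "DQA1*03:02",
               "DQA1*05:05", "DQA1*06:01", "DQA1*04:01", "DQA1*05:01")
DQB1_POOL <- c("DQB1*02:01", "DQB1*03:01", "DQB1*03:03", "DQB1*04:01",
               "DQB1*05:01", "DQB1*05:02", "DQB1*06:01", "DQB1*06:09")

#' Specification for a synthetic eplet registry
#'
#' @param n_drb1,n_drb3,n_drb4,n_drb5,n_dqa1,n_dqb1 alleles per locus.
#' @param dr_core,dqa_core,dqb_core sizes of the always-shared core sets.
#' @param dr_var,dqa_var,dqb_var sizes of the variable eplet pools; these
#'   set the achievable mismatch ranges (DR: 0..`dr_var`; DQ:
#'   0..`dqa_var + dqb_var`).
#' @param dr_fam,dq_fam number of allele families per class (family blocks
#'   partition the variable pool).
#' @param dr_ext,dqa_ext,dqb_ext maximum graded extension into the
#'   neighbouring family block.
#' @return list of class `registry_spec`.
#' @export
registry_spec <- function(n_drb1 = 10, n_drb3 = 3, n_drb4 = 2, n_drb5 = 3,
                          n_dqa1 = 6, n_dqb1 = 8,
                          dr_core = 8, dr_var = 21,
                          dqa_core = 3, dqa_var = 12,
                          dqb_core = 3, dqb_var = 20,
                          dr_fam = 3, dq_fam = 2,
                          dr_ext = 2, dqa_ext = 1, dqb_ext = 1) {
  spec <- as.list(environment())
  stopifnot(n_drb1 >= 1, n_dqa1 >= 1, n_dqb1 >= 1,
            dr_var >= 1, dqa_var >= 1, dqb_var >= 1,
            dr_fam >= 1, dq_fam >= 1)
  structure(spec, class = "registry_spec")
}

## family-block eplet sets: the variable pool is partitioned into n_fam
## contiguous blocks (allele families, mirroring DR/DQ serogroups); an
## allele carries its whole family block plus a graded extension into the
## next block. A donor molecule whose family is absent from the recipient
## repertoire escapes with (most of) its block, reproducing the broad,
## many-zeros molecule-mismatch distributions seen in practice. First
## allele: core-only; last allele: full pool (extremes reachable).
family_sets <- function(n_alleles, pool, n_fam, ext_max) {
  P <- length(pool)
  bounds <- round(seq(0, P, length.out = n_fam + 1))
  block <- function(f) pool[(bounds[f] + 1L):bounds[f + 1L]]
  fam <- integer(n_alleles)
  sets <- vector("list", n_alleles)
  sets[[1]] <- character()
  if (n_alleles >= 2) sets[[n_alleles]] <- pool
  if (n_alleles > 2) {
    for (k in 2:(n_alleles - 1L)) {
      f <- ((k - 2L) %% n_fam) + 1L
      ext <- sample.int(ext_max + 1L, 1L) - 1L
      nxt <- block(f %% n_fam + 1L)
      sets[[k]] <- c(block(f), nxt[seq_len(min(ext, length(nxt)))])
      fam[k] <- f
    }
  }
  list(sets = sets, fam = fam)
}

#' Generate a synthetic eplet registry
#'
#' Deterministic given `seed`; passes all registry invariants; realized
#' pairwise molecule mismatches span 0..`dr_var` (DR) and
#' 0..`dqa_var + dqb_var` (DQ).
#'
#' @param spec a [registry_spec()].
#' @param seed integer seed.
#' @return an `eplet_registry`.
#' @export
generate_fixture_registry <- function(spec = registry_spec(), seed = 1) {
  stopifnot(inherits(spec, "registry_spec"))
  set.seed(seed)
  ids <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  dr_core <- ids("DRc", spec$dr_core)
  dr_var <- ids("DRv", spec$dr_var)
  dqa_core <- ids("DQAc", spec$dqa_core)
  dqa_var <- ids("DQAv", spec$dqa_var)
  dqb_core <- ids("DQBc", spec$dqb_core)
  dqb_var <- ids("DQBv", spec$dqb_var)

  sets <- list()
  families <- integer()
  take <- function(pool, n) pool[seq_len(min(n, length(pool)))]
  add_locus <- function(alleles, core, fs) {
    for (k in seq_along(alleles)) sets[[alleles[k]]] <<- c(core, fs$sets[[k]])
    families[alleles] <<- fs$fam
  }
  drb1 <- take(DRB1_POOL, spec$n_drb1)
  add_locus(drb1, dr_core,
            family_sets(spec$n_drb1, dr_var, spec$dr_fam, spec$dr_ext))
  ## secondary DR loci: a smaller sub-block of their family's DR block
  d345 <- c(take(DRB3_POOL, spec$n_drb3), take(DRB4_POOL, spec$n_drb4),
            take(DRB5_POOL, spec$n_drb5))
  bounds <- round(seq(0, spec$dr_var, length.out = spec$dr_fam + 1))
  for (k in seq_along(d345)) {
    f <- ((k - 1L) %% spec$dr_fam) + 1L
    blk <- dr_var[(bounds[f] + 1L):bounds[f + 1L]]
    len <- sample(seq(3L, length(blk)), 1)
    sets[[d345[k]]] <- c(dr_core, blk[seq_len(len)])
    families[d345[k]] <- f
  }
  add_locus(take(DQA1_POOL, spec$n_dqa1), dqa_core,
            family_sets(spec$n_dqa1, dqa_var, spec$dq_fam, spec$dqa_ext))
  add_locus(take(DQB1_POOL, spec$n_dqb1), dqb_core,
            family_sets(spec$n_dqb1, dqb_var, spec$dq_fam, spec$dqb_ext))

  if (all(!lengths(sets))) stop("registry spec yields empty eplet sets",
                                call. = FALSE)
  reg <- eplet_registry(sets)
  attr(reg, "families") <- families
  reg
}

#' Generate a population haplotype-frequency table
#'
#' Samples distinct DRB1~DRB345~DQA1~DQB1 haplotypes from the registry's
#' alleles (a fraction with a null DRB345 slot, plus forced minimal and
#' maximal haplotypes so the extreme mismatch scores are reachable), then
#' draws population-specific frequencies from a Dirichlet with one boosted
#' anchor haplotype per population.
#'
#' @param registry an `eplet_registry`.
#' @param populations population labels.
#' @param n_haplotypes haplotypes in the pool.
#' @param null_weight sampling weight of the null DRB345 option.
#' @param dq_ld probability that a haplotype's DQA1 family follows its
#'   DQB1 family (within-haplotype linkage disequilibrium; the remainder
#'   are recombinant-like haplotypes producing partial, intermediate-size
#'   DQ mismatches).
#' @param seed integer seed.
#' @return a `haplotype_freq_table`.
#' @export
generate_frequency_table <- function(registry,
                                     populations = c("Chinese", "Malay",
                                                     "Indian"),
                                     n_haplotypes = 40, null_weight = 0.12,
                                     dq_ld = 0.65, seed = 1) {
  set.seed(seed)
  alleles <- names(registry$allele_to_eplets)
  loc <- allele_locus(alleles)
  drb1 <- sort(alleles[loc == "DRB1"])
  d345 <- c("", sort(alleles[loc %in% DRB345]))
  dqa1 <- sort(alleles[loc == "DQA1"])
  dqb1 <- sort(alleles[loc == "DQB1"])
  fam <- attr(registry, "families")
  pick <- function(pool, f) {
    ## family-consistent draw (linkage disequilibrium within a haplotype);
    ## falls back to the whole pool for registries without family metadata
    if (!is.null(fam) && !is.null(f)) {
      cand <- pool[!is.na(fam[pool]) & fam[pool] == f]
      if (length(cand)) return(cand[sample.int(length(cand), 1)])
    }
    pool[sample.int(length(pool), 1)]
  }
  n_fam_of <- function(pool) {
    if (is.null(fam)) return(1L)
    max(1L, fam[pool], na.rm = TRUE)
  }
  draw_hap <- function() {
    fd <- sample.int(n_fam_of(drb1), 1)
    fq_b <- sample.int(n_fam_of(dqb1), 1)
    fq_a <- if (stats::runif(1) < dq_ld) fq_b else
      sample.int(n_fam_of(dqa1), 1)
    c(pick(drb1, fd),
      if (length(d345) == 1L || stats::runif(1) < null_weight) "" else
        pick(d345[-1], fd),
      pick(dqa1, fq_a), pick(dqb1, fq_b))
  }
  ## minimal/maximal alleles are the first/last of each locus pool by
  ## construction in generate_fixture_registry
  forced <- rbind(c(drb1[1], "", dqa1[1], dqb1[1]),
                  c(drb1[length(drb1)], d345[length(d345)],
                    dqa1[length(dqa1)], dqb1[length(dqb1)]))
  haps <- forced
  tries <- 0L
  while (nrow(haps) < n_haplotypes && tries < 50L * n_haplotypes) {
    h <- draw_hap()
    if (!any(apply(haps, 1, identical, y = h))) haps <- rbind(haps, h)
    tries <- tries + 1L
  }
  rows <- list()
  for (p in seq_along(populations)) {
    w <- stats::rgamma(nrow(haps), shape = 2)
    anchor <- if (nrow(haps) > 2L) 2L + ((p - 1L) %% (nrow(haps) - 2L)) else 1L
    w[anchor] <- w[anchor] + max(w)   # distinct anchor per population
    rows[[p]] <- data.frame(population = populations[p],
                            DRB1 = haps[, 1], DRB345 = haps[, 2],
                            DQA1 = haps[, 3], DQB1 = haps[, 4],
                            frequency = w / sum(w),
                            stringsAsFactors = FALSE)
  }
  haplotype_freq_table(do.call(rbind, rows))
}
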