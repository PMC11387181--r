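test_that("generators are deterministic under a fixed seed", {
  r1 <- generate_fixture_registry(seed = 4)
  r2 <- generate_fixture_registry(seed = 4)
  expect_identical(r1$allele_to_eplets, r2$allele_to_eplets)
  f1 <- generate_frequency_table(r1, seed = 4)
  f2 <- generate_frequency_table(r2, seed = 4)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_false(identical(
    as.data.frame(generate_frequency_table(r1, seed = 5)),
    as.data.frame(f1)))
  w <- shared_world()
  s1 <- simulate_cohort(sim_params(n = 30, seed = 9), w$registry, w$freq,
                        w$cache)
  s2 <- simulate_cohort(sim_params(n = 30, seed = 9), w$registry, w$freq,
                        w$cache)
  expect_identical(s1$typing, s2$typing)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$truth, s2$truth)
})

test_that("generated registries satisfy invariants and reach the scales", {
  w <- shared_world()
  reg <- w$registry
  expect_silent(validate_eplet_registry(reg))
  ## exhaustive pairing scan: max achievable DQ molecule mismatch >= 30
  alleles <- names(reg$allele_to_eplets)
  loc <- sub("\\*.*", "", alleles)
  dqa <- alleles[loc == "DQA1"]; dqb <- alleles[loc == "DQB1"]
  dq_sets <- list()
  for (a in dqa) for (b in dqb) {
    dq_sets[[paste(a, b)]] <- union(eplets_for_allele(reg, a),
                                    eplets_for_allele(reg, b))
  }
  best <- 0
  for (d in dq_sets) for (r in dq_sets) {
    best <- max(best, length(setdiff(d, r)))
  }
  expect_gte(best, 30)
  ## realized (haplotype-pool) ranges cover the printed spans
  expect_equal(min(w$cache$dr_max), 0)
  expect_gte(max(w$cache$dr_max), 20)
  expect_equal(min(w$cache$dq_max), 0)
  expect_gte(max(w$cache$dq_max), 30)
})

test_that("one allele per locus collapses all mismatches to zero", {
  spec <- registry_spec(n_drb1 = 1, n_drb3 = 0, n_drb4 = 0, n_drb5 = 0,
                        n_dqa1 = 1, n_dqb1 = 1)
  reg <- generate_fixture_registry(spec, seed = 2)
  freq <- generate_frequency_table(reg, seed = 2, n_haplotypes = 2)
  cache <- build_mismatch_cache(reg, freq)
  expect_true(all(cache$dr_max == 0))
  expect_true(all(cache$dq_max == 0))
})

test_that("frequency tables are proper distributions with distinct modes", {
  w <- shared_world()
  freq <- w$freq
  sums <- tapply(freq$frequency, freq$population, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  tops <- tapply(seq_len(nrow(freq)), freq$population, function(i) {
    sub <- freq[i, ]
    hs <- paste(sub$DRB1, sub$DRB345, sub$DQA1, sub$DQB1)
    hs[which.max(sub$frequency)]
  })
  expect_equal(length(unique(tops)), length(tops))
})

test_that("simulated cohorts match their stated mixes and structure", {
  w <- shared_world()
  p <- sim_params(n = 1500, seed = 21)
  sim <- simulate_cohort(p, w$registry, w$freq, w$cache)
  eth <- prop.table(table(sim$records$ethnicity))
  for (nm in names(p$ethnicity_mix)) {
    expect_lt(abs(eth[[nm]] - p$ethnicity_mix[[nm]]),
              3 * sqrt(p$ethnicity_mix[[nm]] / p$n) + 0.01)
  }
  cni <- prop.table(table(sim$records$cni))
  expect_lt(abs(cni[["cyclosporine"]] - 0.71), 0.05)
  expect_true(all(sim$records$follow_up_years > 0))
  expect_true(all(sim$detections$day >= 0))
  ## typing frame parses and validates end-to-end
  st <- parse_typing_table(sim$typing[1:40, ])
  expect_length(st, 40)
})

test_that("hazards increase across mismatch tertiles", {
  w <- shared_world()
  p <- sim_params(n = 4000, seed = 22, lowres_fraction = 0)
  sim <- simulate_cohort(p, w$registry, w$freq, w$cache)
  t <- sim$truth
  strata <- cut(t$dq_max, breaks = c(-1, 0, 14, 33),
                labels = c("zero", "mid", "high"))
  rate <- tapply(t$latent_t_dq <= t$follow_up_years, strata, mean)
  expect_true(all(diff(rate) > 0))
})

test_that("null effects and degenerate molecule-level labels behave", {
  ## beta = 0: per-eplet HR near 1
  w <- shared_world()
  p <- sim_params(n = 2000, seed = 23, beta_dr = 0, beta_dq = 0,
                  cni_hr = 1, lambda0_dr = 0.05, exact_times = TRUE,
                  lowres_fraction = 0)
  sim <- simulate_cohort(p, w$registry, w$freq, w$cache)
  t <- sim$truth
  ev <- as.integer(t$latent_t_dr <= t$follow_up_years)
  fit <- cox_fit(survival::Surv(pmin(t$latent_t_dr, t$follow_up_years),
                                ev) ~ dr_max, t)
  expect_equal(fit$table$hr[1], 1, tolerance = 0.03)
  ## logistic slope 0: AUC ~ 0.5
  d <- simulate_molecule_level_dataset(
    molsim_params(n_pairs = 2000, model = "logistic", intercept = -2,
                  slope = 0), seed = 24)
  r <- roc_auc(d$molecules$score, d$molecules$label)
  expect_equal(r$auc, 0.5, tolerance = 0.03)
  ## all-zero labels: single-class error downstream
  d0 <- simulate_molecule_level_dataset(
    molsim_params(n_pairs = 50, p_low = 0, p_high = 0), seed = 25)
  expect_error(roc_auc(d0$molecules$score, d0$molecules$label),
               "both classes")
})

test_that("the mismatch cache agrees with the mismatch engine", {
  w <- shared_world()
  set.seed(26)
  H <- nrow(w$cache$haps)
  for (k in 1:15) {
    dh <- sort(sample(H, 2, TRUE)); rh <- sort(sample(H, 2, TRUE))
    don <- subject_typing("D", "donor", "p", "X",
                          epletmm:::cache_typing_alleles(w$cache, dh[1], dh[2]))
    rec <- subject_typing("R", "recipient", "p", "X",
                          epletmm:::cache_typing_alleles(w$cache, rh[1], rh[2]))
    sm <- recipient_mismatch_summary(don, rec, w$registry)
    dc <- w$cache$pair_index[dh[1], dh[2]]
    rc <- w$cache$pair_index[rh[1], rh[2]]
    expect_identical(sm$dr_max, w$cache$dr_max[dc, rc])
    expect_identical(sm$dq_max, w$cache$dq_max[dc, rc])
  }
})
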