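## Hand-built toy registry: small enough that every expected value below
## can be checked by eye.
##   DR eplets  r1..r6 (beta), DQ alpha qa1,qa2, DQ beta qb1..qb3
toy_registry <- function() {
  eplet_registry(list(
    "DRB1*01:01" = c("r1", "r2"),
    "DRB1*04:05" = c("r2", "r3", "r4"),
    "DRB1*15:01" = c("r1", "r4", "r6"),
    "DRB3*02:02" = c("r5"),
    "DRB5*01:01" = c("r4", "r5", "r6"),
    "DQA1*01:02" = c("qa1"),
    "DQA1*03:02" = c("qa1", "qa2"),
    "DQB1*05:02" = c("qb1", "qb2"),
    "DQB1*06:01" = c("qb3"),
    "DQB1*02:01" = character()))
}

toy_typing <- function(id = "S1", role = "recipient", pair = "p1",
                       eth = "Chinese",
                       drb1 = c("DRB1*01:01", "DRB1*04:05"),
                       drb345 = c("DRB3*02:02", ""),
                       dqa1 = c("DQA1*01:02", "DQA1*03:02"),
                       dqb1 = c("DQB1*05:02", "DQB1*06:01")) {
  subject_typing(id, role, pair, eth, list(
    DRB1_1 = drb1[1], DRB1_2 = drb1[2],
    DRB345_1 = drb345[1], DRB345_2 = drb345[2],
    DQA1_1 = dqa1[1], DQA1_2 = dqa1[2],
    DQB1_1 = dqb1[1], DQB1_2 = dqb1[2]))
}

toy_freq <- function() {
  haplotype_freq_table(data.frame(
    population = "Chinese",
    DRB1 = c("DRB1*01:01", "DRB1*04:05", "DRB1*15:01"),
    DRB345 = c("", "DRB3*02:02", "DRB5*01:01"),
    DQA1 = c("DQA1*01:02", "DQA1*03:02", "DQA1*01:02"),
    DQB1 = c("DQB1*05:02", "DQB1*06:01", "DQB1*02:01"),
    frequency = c(0.5, 0.3, 0.2),
    stringsAsFactors = FALSE))
}

## random small registry + two typings drawn from it, for property tests
random_world <- function(n_dr_ep = 8, n_dq_ep = 8) {
  dr_ep <- sprintf("d%02d", seq_len(n_dr_ep))
  qa_ep <- sprintf("a%02d", seq_len(n_dq_ep))
  qb_ep <- sprintf("b%02d", seq_len(n_dq_ep))
  rs <- function(pool) pool[runif(length(pool)) < runif(1, 0.2, 0.8)]
  drb1 <- sprintf("DRB1*%02d:01", 1:4)
  drb345 <- c("DRB3*01:01", "DRB4*01:01", "DRB5*01:01")
  dqa1 <- sprintf("DQA1*%02d:01", 1:3)
  dqb1 <- sprintf("DQB1*%02d:01", 1:4)
  sets <- c(
    stats::setNames(lapply(drb1, function(a) rs(dr_ep)), drb1),
    stats::setNames(lapply(drb345, function(a) rs(dr_ep)), drb345),
    stats::setNames(lapply(dqa1, function(a) rs(qa_ep)), dqa1),
    stats::setNames(lapply(dqb1, function(a) rs(qb_ep)), dqb1))
  reg <- eplet_registry(sets)
  draw_typing <- function(id, role) {
    d345 <- sample(c(drb345, "", ""), 2)
    subject_typing(id, role, "p1", "X", list(
      DRB1_1 = sample(drb1, 1), DRB1_2 = sample(drb1, 1),
      DRB345_1 = d345[1], DRB345_2 = d345[2],
      DQA1_1 = sample(dqa1, 1), DQA1_2 = sample(dqa1, 1),
      DQB1_1 = sample(dqb1, 1), DQB1_2 = sample(dqb1, 1)))
  }
  list(registry = reg, donor = draw_typing("D", "donor"),
       recipient = draw_typing("R", "recipient"))
}

## brute-force mismatch oracle: per-eplet membership scan, no set algebra
brute_mismatch_count <- function(donor_eplets, recipient_mols) {
  n <- 0L
  for (e in donor_eplets) {
    found <- FALSE
    for (i in seq_len(nrow(recipient_mols))) {
      if (e %in% recipient_mols$eplets[[i]]) { found <- TRUE; break }
    }
    if (!found) n <- n + 1L
  }
  n
}

## generated world shared by simulator/pipeline/acceptance tests
shared_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      reg <- generate_fixture_registry(seed = 1)
      freq <- generate_frequency_table(reg, seed = 1)
      w <<- list(registry = reg, freq = freq,
                 cache = build_mismatch_cache(reg, freq))
    }
    w
  }
})
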