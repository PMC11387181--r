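mk_records <- function(n = 4) {
  df <- data.frame(pair_id = paste0("p", seq_len(n)),
                   follow_up_years = rep(6, n),
                   primary_non_function = FALSE, spk = FALSE,
                   abo_incompatible = FALSE, pretransplant_dsa = FALSE,
                   positive_crossmatch = FALSE,
                   inadequate_assessment = FALSE, early_dsa_14d = FALSE,
                   stringsAsFactors = FALSE)
  df
}

test_that("exclusion filters tally by first matching reason", {
  rec <- mk_records(5)
  rec$abo_incompatible[2] <- TRUE
  rec$primary_non_function[3] <- TRUE
  rec$abo_incompatible[3] <- TRUE        # first reason wins
  rec$early_dsa_14d[4] <- TRUE
  out <- apply_cohort_filters(rec)
  expect_equal(nrow(out$retained), 2)
  expect_equal(sum(out$tally), 3)
  expect_equal(out$tally[["abo_incompatible"]], 1L)
  expect_equal(out$tally[["primary_non_function"]], 1L)
  expect_equal(out$tally[["early_dsa_14d"]], 1L)
  expect_equal(out$excluded$reason[out$excluded$pair_id == "p3"],
               "primary_non_function")
  # conservation: retained + excluded = input
  expect_equal(nrow(out$retained) + nrow(out$excluded), nrow(rec))
})

test_that("memory-window DSA flags respect the MFI cutoff", {
  rec <- mk_records(3)
  det <- data.frame(pair_id = c("p1", "p2", "p3"),
                    day = c(10, 10, 100),
                    specificity = "DQB1*05:02",
                    mfi = c(800, 450, 900), stringsAsFactors = FALSE)
  fl <- flag_memory_dsa(rec, det)
  expect_equal(fl$early_dsa_14d, c(TRUE, FALSE, FALSE))
})

test_that("dnDSA events follow the MFI/window/attribution rule", {
  reg <- toy_registry()
  mols <- enumerate_molecules(toy_typing("D", "donor"), reg)
  rec <- mk_records(1)
  det <- data.frame(pair_id = "p1",
                    day = c(400, 900, 5, 200),
                    specificity = c("DQB1*05:02", "DRB1*04:05",
                                    "DQB1*05:02", "DQB1*06:01"),
                    mfi = c(800, 600, 2000, 450), stringsAsFactors = FALSE)
  ev <- define_dndsa_events(rec[1, ], det, mols)
  expect_equal(nrow(ev), 2)
  dq <- ev[ev$locus == "DQ", ]
  dr <- ev[ev$locus == "DR", ]
  # day-5 hit is memory (ignored), day-200 hit is sub-cutoff
  expect_equal(dq$event, 1L)
  expect_equal(dq$time_years, 400 / 365.25)
  expect_equal(dr$event, 1L)
  expect_equal(dr$time_years, 900 / 365.25)
})

test_that("sub-cutoff and third-party detections censor at follow-up", {
  reg <- toy_registry()
  mols <- enumerate_molecules(toy_typing("D", "donor"), reg)
  rec <- mk_records(1)
  low <- data.frame(pair_id = "p1", day = 400, specificity = "DQB1*05:02",
                    mfi = 450, stringsAsFactors = FALSE)
  ev <- define_dndsa_events(rec[1, ], low, mols)
  expect_equal(ev$event, c(0L, 0L))
  expect_equal(ev$time_years, c(6, 6))
  third <- data.frame(pair_id = "p1", day = 400,
                      specificity = "DQB1*03:01", mfi = 5000,
                      stringsAsFactors = FALSE)
  ev2 <- define_dndsa_events(rec[1, ], third, mols)
  expect_equal(ev2$event, c(0L, 0L))
  ## missing MFI: screening-only by default, error on request
  nodata <- data.frame(pair_id = "p1", day = 400,
                       specificity = "DQB1*05:02", mfi = NA,
                       stringsAsFactors = FALSE)
  ev3 <- define_dndsa_events(rec[1, ], nodata, mols)
  expect_equal(ev3$event, c(0L, 0L))
  expect_error(define_dndsa_events(rec[1, ], nodata, mols,
                                   missing_mfi = "error"), "missing MFI")
})

test_that("molecule-level ROC dataset labels the attacked molecule", {
  reg <- toy_registry()
  don <- toy_typing("D", "donor")
  rcp <- toy_typing("R", "recipient", drb1 = c("DRB1*15:01", "DRB1*15:01"),
                    drb345 = c("", ""), dqa1 = c("DQA1*01:02", "DQA1*01:02"),
                    dqb1 = c("DQB1*02:01", "DQB1*02:01"))
  sm <- list(p1 = recipient_mismatch_summary(don, rcp, reg))
  mols <- list(p1 = enumerate_molecules(don, reg))
  det <- data.frame(pair_id = "p1", day = 500, specificity = "DQB1*05:02",
                    mfi = 900, stringsAsFactors = FALSE)
  md <- molecule_roc_data(sm, mols, det)
  expect_equal(nrow(md), nrow(sm$p1$molecules))
  hit <- md[md$label == 1, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$locus_class, "DQ")
  expect_equal(hit$score,
               sm$p1$molecules$count[sm$p1$molecules$molecule_id ==
                                       hit$molecule_id])
})
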