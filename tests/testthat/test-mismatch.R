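test_that("molecule mismatch is donor-minus-recipient-union", {
  reg <- toy_registry()
  donor <- toy_typing("D", "donor", drb1 = c("DRB1*04:05", "DRB1*04:05"),
                      drb345 = c("", ""))
  rec <- toy_typing("R", "recipient", drb1 = c("DRB1*01:01", "DRB1*01:01"),
                    drb345 = c("", ""))
  dmols <- enumerate_molecules(donor, reg)
  rmols <- enumerate_molecules(rec, reg)
  mm <- molecule_eplet_mismatch(dmols[1, ], rmols[rmols$locus_class == "DR", ],
                                reg)
  # donor {r2,r3,r4} minus recipient union {r1,r2} = {r3,r4}
  expect_setequal(mm$mismatched_eplets, c("r3", "r4"))
  expect_equal(mm$count, 2)
  # donor allele carried by the recipient: count 0
  mm0 <- molecule_eplet_mismatch(rmols[1, ], rmols[rmols$locus_class == "DR", ],
                                 reg)
  expect_equal(mm0$count, 0)
  # locus-class mixing is a contract error
  expect_error(molecule_eplet_mismatch(dmols[1, ],
                                       rmols[rmols$locus_class == "DQ", ],
                                       reg), "class mixing")
})

test_that("recipient summary maxima, self-match, and directionality", {
  reg <- toy_registry()
  self <- recipient_mismatch_summary(toy_typing("D", "donor"),
                                     toy_typing("R", "recipient"), reg)
  expect_equal(self$dr_max, 0)
  expect_equal(self$dq_max, 0)
  # asymmetric pair: recipient carries a superset at DR
  donor <- toy_typing("D", "donor", drb1 = c("DRB1*01:01", "DRB1*01:01"),
                      drb345 = c("", ""))
  rec <- toy_typing("R", "recipient", drb1 = c("DRB1*01:01", "DRB1*04:05"),
                    drb345 = c("DRB5*01:01", ""))
  fwd <- recipient_mismatch_summary(donor, rec, reg)
  bwd <- recipient_mismatch_summary(rec, donor, reg)
  expect_equal(fwd$dr_max, 0)
  expect_gt(bwd$dr_max, 0)
})

test_that("mismatch engine equals the brute-force oracle on random worlds", {
  set.seed(202)
  for (i in 1:200) {
    w <- random_world()
    dmols <- enumerate_molecules(w$donor, w$registry)
    rmols <- enumerate_molecules(w$recipient, w$registry)
    for (k in seq_len(nrow(dmols))) {
      cls <- dmols$locus_class[k]
      rsub <- rmols[rmols$locus_class == cls, ]
      got <- molecule_eplet_mismatch(dmols[k, ], rsub, w$registry)$count
      expect_identical(got, brute_mismatch_count(dmols$eplets[[k]], rsub))
    }
  }
})

test_that("monotonicity, bounds, and null neutrality", {
  set.seed(303)
  for (i in 1:40) {
    w <- random_world()
    dmols <- enumerate_molecules(w$donor, w$registry)
    rmols <- enumerate_molecules(w$recipient, w$registry)
    base <- recipient_mismatch_summary(w$donor, w$recipient, w$registry)
    for (k in seq_len(nrow(dmols))) {
      cnt <- molecule_eplet_mismatch(
        dmols[k, ], rmols[rmols$locus_class == dmols$locus_class[k], ],
        w$registry)$count
      expect_gte(cnt, 0)
      expect_lte(cnt, length(dmols$eplets[[k]]))
    }
    ## adding any molecule to the recipient repertoire never increases a
    ## donor molecule's count
    dr_d <- dmols[dmols$locus_class == "DR", ]
    rme <- rmols[rmols$locus_class == "DR", ]
    for (k in seq_len(nrow(dr_d))) {
      before <- molecule_eplet_mismatch(dr_d[k, ], rme, w$registry)$count
      add <- dr_d[sample.int(nrow(dr_d), 1), ]
      after <- molecule_eplet_mismatch(dr_d[k, ], rbind(rme, add),
                                       w$registry)$count
      expect_lte(after, before)
    }
    ## deleting a donor DRB345 allele can only lower dr_max
    dal <- stats::setNames(as.list(w$donor$calls$value), w$donor$calls$slot)
    if (!is.na(dal$DRB345_1)) {
      dal$DRB345_1 <- NA
      donor2 <- subject_typing("D2", "donor", "p1", "X", dal)
      nulled <- recipient_mismatch_summary(donor2, w$recipient, w$registry)
      expect_lte(nulled$dr_max, base$dr_max)
    }
  }
})

test_that("antigen mismatch counts first-field groups", {
  reg <- toy_registry()
  a <- toy_typing("A", "donor")
  expect_equal(antigen_mismatch(a, toy_typing("B", "recipient"), "DRB1"), 0)
  d <- toy_typing("D", "donor", drb1 = c("DRB1*04:05", "DRB1*15:01"))
  r <- toy_typing("R", "recipient", drb1 = c("DRB1*04:05", "DRB1*04:05"))
  expect_equal(antigen_mismatch(d, r, "DRB1"), 1)
  d2 <- toy_typing("D", "donor", dqb1 = c("DQB1*02:01", "DQB1*05:02"))
  r2 <- toy_typing("R", "recipient", dqb1 = c("DQB1*06:01", "DQB1*06:01"))
  expect_equal(antigen_mismatch(d2, r2, "DQB1"), 2)
})

test_that("DSA specificities attribute to the right donor molecules", {
  reg <- toy_registry()
  mols <- enumerate_molecules(toy_typing("D", "donor"), reg)
  hit <- attribute_dsa_to_molecules("DQB1*05:02", mols)
  expect_length(hit, 1)
  expect_match(hit, "DQ_heterodimer")
  # one-field allele form: first-field prefix rule
  expect_length(attribute_dsa_to_molecules("DRB1*04", mols), 1)
  # serologic label resolved by prefix; rejected under the strict config
  expect_length(attribute_dsa_to_molecules("DR4", mols), 1)
  expect_error(attribute_dsa_to_molecules("DR4", mols,
                                          serologic = "reject"), "rejected")
  # out-of-class specificity: empty with warning
  expect_warning(out <- attribute_dsa_to_molecules("A*02:01", mols),
                 "outside HLA-DR/DQ")
  expect_length(out, 0)
  # non-donor-directed DR/DQ allele: silently empty
  expect_length(attribute_dsa_to_molecules("DRB1*15:01", mols), 0)
  expect_error(attribute_dsa_to_molecules("??", mols), "unparseable")
})
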