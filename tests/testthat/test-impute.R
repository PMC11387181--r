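## independent brute-force imputation oracle: enumerate every ordered
## haplotype pair, check per-locus compatibility by explicit permutation,
## maximize the frequency product, break ties lexicographically
oracle_impute <- function(typing, freq, population) {
  rows <- freq[freq$population == population, , drop = FALSE]
  hs <- paste(rows$DRB1, rows$DRB345, rows$DQA1, rows$DQB1, sep = "~")
  o <- order(hs); rows <- rows[o, ]; hs <- hs[o]
  calls <- typing$calls
  compat1 <- function(k, a) {
    v <- calls$value[k]; r <- calls$resolution[k]
    if (r == "two_field") return(nzchar(a) && a == v)
    if (r == "low_res") {
      return(nzchar(a) && sub("\\*.*", "", a) == sub("\\*.*", "", v) &&
               sub(".*\\*([0-9]+).*", "\\1", a) ==
               sub(".*\\*([0-9]+).*", "\\1", v))
    }
    if (r == "null") return(!nzchar(a))
    TRUE
  }
  loc <- list(c(1, 2, "DRB1"), c(3, 4, "DRB345"), c(5, 6, "DQA1"),
              c(7, 8, "DQB1"))
  best <- NULL
  for (i in seq_len(nrow(rows))) for (j in seq_len(nrow(rows))) {
    if (j < i) next
    ok <- TRUE
    for (g in loc) {
      a <- as.integer(g[1]); b <- as.integer(g[2]); L <- g[3]
      ai <- rows[[L]][i]; aj <- rows[[L]][j]
      if (!((compat1(a, ai) && compat1(b, aj)) ||
            (compat1(a, aj) && compat1(b, ai)))) { ok <- FALSE; break }
    }
    if (!ok) next
    sc <- rows$frequency[i] * rows$frequency[j]
    key <- paste(hs[i], hs[j], sep = "|")
    if (is.null(best) || sc > best$sc ||
        (sc == best$sc && key < best$key)) {
      best <- list(i = i, j = j, sc = sc, key = key)
    }
  }
  if (is.null(best)) return(NULL)
  rows[c(best$i, best$j), c("DRB1", "DRB345", "DQA1", "DQB1")]
}

test_that("forced and argmax completions match hand-computed answers", {
  freq <- toy_freq()
  # low-res DQB1*05: only the first haplotype carries a DQB1*05 group
  st <- toy_typing("S", "recipient",
                   drb1 = c("DRB1*01:01", "DRB1*01:01"),
                   drb345 = c("", ""),
                   dqa1 = c("", ""), dqb1 = c("DQB1*05", "DQB1*05"))
  out <- impute_two_field(st, freq, "Chinese")
  expect_true(is_two_field(out))
  expect_equal(out$calls$value[out$calls$slot == "DQB1_1"], "DQB1*05:02")
  # two compatible completions of low-res DRB1*04, frequencies 0.30 vs
  # 0.10: the 0.30 haplotype is chosen
  freq2 <- haplotype_freq_table(data.frame(
    population = "X",
    DRB1 = c("DRB1*04:01", "DRB1*04:05", "DRB1*01:01"),
    DRB345 = "", DQA1 = "DQA1*01:02", DQB1 = "DQB1*05:02",
    frequency = c(0.30, 0.10, 0.60), stringsAsFactors = FALSE))
  st2 <- toy_typing("S2", "recipient",
                    drb1 = c("DRB1*01:01", "DRB1*04"),
                    drb345 = c("", ""), dqa1 = c("", ""),
                    dqb1 = c("DQB1*05:02", ""))
  out2 <- impute_two_field(st2, freq2, "X")
  drb1_out <- out2$calls$value[grepl("DRB1", out2$calls$slot)]
  expect_setequal(drb1_out, c("DRB1*01:01", "DRB1*04:01"))
})

test_that("imputation is idempotent, deterministic, and errors cleanly", {
  freq <- toy_freq()
  st <- toy_typing(drb345 = c("DRB3*02:02", ""))
  expect_identical(impute_two_field(st, freq, "Chinese"), st)
  # no compatible haplotype
  bad <- toy_typing("S", "recipient", drb1 = c("DRB1*15:01", "DRB1*15:01"),
                    drb345 = c("", ""), dqa1 = c("", ""),
                    dqb1 = c("DQB1*05:02", "DQB1*05:02"))
  expect_error(impute_two_field(bad, freq, "Chinese"),
               "no compatible haplotype")
  # unmatched population falls back to the pooled table
  st4 <- toy_typing("S4", "recipient", drb1 = c("DRB1*01:01", ""),
                    drb345 = c("", ""), dqa1 = c("", ""),
                    dqb1 = c("", ""))
  out <- impute_two_field(st4, freq, "Martian")
  expect_true(is_two_field(out))
})

test_that("ties break lexicographically on the haplotype strings", {
  freq <- haplotype_freq_table(data.frame(
    population = "X",
    DRB1 = c("DRB1*04:05", "DRB1*04:01"),
    DRB345 = c("", ""),
    DQA1 = c("DQA1*01:02", "DQA1*01:02"),
    DQB1 = c("DQB1*05:02", "DQB1*05:02"),
    frequency = c(0.5, 0.5), stringsAsFactors = FALSE))
  st <- toy_typing("S", "donor", drb1 = c("DRB1*04", "DRB1*04"),
                   drb345 = c("", ""), dqa1 = c("", ""),
                   dqb1 = c("DQB1*05:02", "DQB1*05:02"))
  out <- impute_two_field(st, freq, "X")
  # DRB1*04:01~... < DRB1*04:05~...; homozygous 04:01 pair sorts first
  expect_equal(sort(out$calls$value[grepl("DRB1", out$calls$slot)]),
               c("DRB1*04:01", "DRB1*04:01"))
})

test_that("imputation equals the exhaustive-enumeration oracle", {
  set.seed(101)
  for (rep in 1:30) {
    drb1 <- sprintf("DRB1*%02d:0%d", sample(1:16, 4), sample(1:5, 4, TRUE))
    d345 <- c("", "DRB3*01:01", "DRB4*01:03", "DRB5*01:01")
    dqa1 <- sprintf("DQA1*0%d:01", sample(1:6, 3))
    dqb1 <- sprintf("DQB1*0%d:0%d", sample(2:6, 3, TRUE), sample(1:4, 3, TRUE))
    H <- sample(4:10, 1)
    tab <- data.frame(population = "X",
                      DRB1 = sample(drb1, H, TRUE),
                      DRB345 = sample(d345, H, TRUE),
                      DQA1 = sample(dqa1, H, TRUE),
                      DQB1 = sample(dqb1, H, TRUE),
                      frequency = runif(H), stringsAsFactors = FALSE)
    tab <- tab[!duplicated(paste(tab$DRB1, tab$DRB345, tab$DQA1, tab$DQB1)), ]
    tab$frequency <- tab$frequency / (sum(tab$frequency) + 0.2)
    freq <- haplotype_freq_table(tab)
    ## observed typing: degrade a random genotype drawn from the table
    gi <- sample(nrow(tab), 2, TRUE)
    h1 <- tab[gi[1], ]; h2 <- tab[gi[2], ]
    degrade <- function(x) {
      if (!nzchar(x)) return(x)
      if (runif(1) < 0.4) paste0(sub("\\*.*", "", x), "*",
                                 sub(".*\\*([0-9]+).*", "\\1", x))
      else if (runif(1) < 0.2) "" else x
    }
    st <- subject_typing("S", "recipient", "p", "X", list(
      DRB1_1 = degrade(h1$DRB1), DRB1_2 = degrade(h2$DRB1),
      DRB345_1 = h1$DRB345, DRB345_2 = h2$DRB345,
      DQA1_1 = degrade(h1$DQA1), DQA1_2 = degrade(h2$DQA1),
      DQB1_1 = degrade(h1$DQB1), DQB1_2 = degrade(h2$DQB1)))
    got <- impute_two_field(st, freq, "X")
    want <- oracle_impute(st, freq, "X")
    expect_false(is.null(want))
    got_haps <- sort(c(paste(got$calls$value[c(1, 3, 5, 7)], collapse = "~"),
                       paste(got$calls$value[c(2, 4, 6, 8)], collapse = "~")))
    want_haps <- sort(paste(want$DRB1, want$DRB345, want$DQA1, want$DQB1,
                            sep = "~"))
    got_haps <- gsub("NA", "", got_haps)
    expect_equal(got_haps, want_haps)
  }
})
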