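test_that("duplex scoring weights match, G:U and adjacency as defined", {
  m <- 21
  perfect <- strrep("M", m)
  expect_equal(score_duplex(perfect)$mismatch_total, 0)
  one_gu <- paste0(strrep("M", 4), "G", strrep("M", m - 5))
  expect_equal(score_duplex(one_gu)$mismatch_total, 0.5)
  adj <- paste0("MM", "XX", strrep("M", m - 4))
  sc <- score_duplex(adj)
  expect_equal(sc$mismatch_total, 2)
  expect_equal(sc$adjacent_max, 2)
  # seed-region accounting (positions 2-12)
  seeded <- paste0("M", "X", strrep("M", 10), "X", strrep("M", m - 13))
  sc2 <- score_duplex(seeded)
  expect_equal(sc2$region_2_12, 1)
  expect_equal(sc2$region_1_12, 1)
})

test_that("the six rules accept and reject per their definitions", {
  m <- 21
  pm <- -50
  perfect <- strrep("M", m)
  r <- apply_rules(perfect, duplex_mfe = pm, perfect_mfe = pm)
  expect_true(r$accepted)
  expect_equal(r$mfe_ratio, 1)
  # mismatch at position 10 kills R4 alone among the pairing rules
  at10 <- paste0(strrep("M", 9), "X", strrep("M", m - 10))
  r10 <- apply_rules(at10, duplex_mfe = pm + 3, perfect_mfe = pm)
  expect_false(r10$R4)
  expect_false(r10$accepted)
  # five scattered mismatches exceed the global limit
  five <- paste0("M", "X", "MM", "X", "MM", "X", "MMMM", "X", "MMM", "X",
                 strrep("M", m - 16))
  r5 <- apply_rules(five, duplex_mfe = pm + 12, perfect_mfe = pm)
  expect_false(r5$R1)
  # three adjacent G:U in the seed trip the adjacency rules
  gus <- paste0("MM", "GGG", strrep("M", m - 5))
  rg <- apply_rules(gus, duplex_mfe = pm - 3, perfect_mfe = pm)
  expect_false(rg$R2)
  expect_false(rg$R3)
  # a weak duplex fails the energy-ratio rule
  weak <- paste0(strrep("M", 13), "XXXX", strrep("M", 4))
  rw <- apply_rules(weak, duplex_mfe = -32, perfect_mfe = -50)
  expect_false(rw$R6)
  expect_error(apply_rules(perfect, -10, 0), "perfect_mfe")
})

test_that("scanning finds a perfect-complement site with ratio 1", {
  set.seed(21)
  mir <- rseq(21)
  tx <- c(t1 = paste0(rseq(50), revcomp(mir), rseq(40)))
  hits <- scan_targets(c(m1 = mir), tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatch_total, 0)
  expect_equal(hits$mfe_ratio, 1)
  expect_equal(hits$site_start, 50)
  expect_equal(hits$site_end, 71)
  # cleavage position is opposite miRNA position 10
  expect_equal(hits$predicted_cleavage, hits$site_end - 10)
  expect_error(scan_targets(c(short = rseq(12)), tx), "15 nt")
})

test_that("planted conformant sites are reported and an R4 violation is not", {
  set.seed(22)
  mir <- rseq(21)
  site_ok <- revcomp(mir)
  site_bad <- site_ok
  # mismatch opposite miRNA position 10: site position (21-10) 0-based 11
  mb <- substr(mir, 10, 10)
  substr(site_bad, 12, 12) <- mb  # same base cannot pair
  txs <- c(t1 = paste0(rseq(30), site_ok, rseq(20)),
           t2 = paste0(rseq(10), site_bad, rseq(25)),
           t3 = rseq(60), t4 = rseq(55),
           t5 = paste0(rseq(5), site_ok, rseq(30)), t6 = rseq(58))
  hits <- scan_targets(c(m1 = mir), txs)
  expect_setequal(hits$transcript_id, c("t1", "t5"))
  expect_equal(nrow(hits), 2L)
})

test_that("scan equals exhaustive enumeration with independent rule checks", {
  set.seed(23)
  for (rep in 1:6) {
    mir <- rseq(19 + (rep %% 3))
    tx <- rseq(60)
    if (rep %% 2 == 0) {
      # plant a degraded site to exercise near-threshold paths
      site <- revcomp(mir)
      p <- 14 + rep
      substr(site, p, p) <- substr(site, p, p)  # no-op keeps determinism
      tx <- paste0(substr(tx, 1, 20), site,
                   substr(tx, 21 + nchar(site), 60))
    }
    got <- scan_targets(c(m = mir), c(t = tx))
    want <- oracle_scan(mir, tx)
    # compare accepted site sets after the package's overlap collapse:
    # every reported hit must be in the oracle set, and every oracle site
    # must overlap a reported hit
    if (nrow(want) == 0) {
      expect_equal(nrow(got), 0L, info = paste("rep", rep))
    } else {
      expect_gt(nrow(got), 0)
      for (i in seq_len(nrow(got))) {
        expect_true(any(want$site_start == got$site_start[i] &
                          want$site_end == got$site_end[i] &
                          abs(want$mismatch_total - got$mismatch_total[i]) < 1e-9),
                    info = paste("rep", rep))
      }
      for (j in seq_len(nrow(want))) {
        expect_true(any(got$site_start < want$site_end[j] &
                          got$site_end > want$site_start[j]),
                    info = paste("rep", rep))
      }
    }
  }
})

test_that("one gene hosts hits from several distinct miRNAs", {
  set.seed(24)
  m1 <- rseq(21); m2 <- rseq(22)
  tx <- c(g = paste0(rseq(10), revcomp(m1), rseq(15), revcomp(m2), rseq(10)))
  hits <- scan_targets(c(a = m1, b = m2), tx)
  expect_setequal(hits$mirna_id, c("a", "b"))
  expect_equal(nrow(hits), 2L)
  # sorted by ascending mismatches then descending ratio
  expect_true(!is.unsorted(hits$mismatch_total))
})
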