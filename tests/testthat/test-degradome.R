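test_that("profiles accumulate tag 5' ends with counts and conserve totals", {
  set.seed(31)
  t1 <- rseq(300); t2 <- rseq(250)
  shared <- substr(t1, 101, 120)
  t2 <- paste0(substr(t2, 1, 50), shared, substr(t2, 71, 250))
  tags <- setNames(c(shared, substr(t1, 31, 50)),
                   c("dtag1_x3", "dtag2_x2"))
  prof <- build_profiles(tags, c(t1 = t1, t2 = t2))
  expect_equal(prof$t1$depth[101], 3L)   # 1-based index = 0-based pos 100
  expect_equal(prof$t1$depth[31], 2L)
  expect_equal(prof$t2$depth[51], 3L)    # tag matching two transcripts
  expect_equal(sum(prof$t1$depth), prof$t1$total_tags)
  expect_equal(sum(prof$t2$depth), prof$t2$total_tags)
  # no matching tags: all-zero profile
  prof0 <- build_profiles(setNames(rseq(20), "dtagx_x5"), c(t1 = t1))
  expect_equal(sum(prof0$t1$depth), 0L)
  # tags shorter than 18 nt are ignored
  prof_short <- build_profiles(setNames(substr(t1, 1, 15), "s_x9"),
                               c(t1 = t1))
  expect_equal(sum(prof_short$t1$depth), 0L)
})

test_that("peak categories follow their definitions", {
  expect_equal(categorize(c(0, 0, 9, 1, 1), 2), 0L)   # unique max > median
  expect_equal(categorize(c(5, 5, 0, 0), 0), 1L)      # non-unique max
  expect_equal(categorize(c(9, 4, 2, 2, 0), 1), 2L)   # above median, below max
  expect_equal(categorize(c(9, 4, 2, 2, 0), 2), 3L)   # at/below median
  expect_equal(categorize(c(9, 4, 2, 1, 0), 3), 4L)   # depth exactly 1
  expect_true(is.na(categorize(c(9, 0, 2), 1)))       # zero depth: undefined
  expect_error(categorize(c(1, 2, 3), 5), "out of range")
})

test_that("dinucleotide shuffles preserve dinucleotide composition and ends", {
  set.seed(32)
  for (i in 1:20) {
    s <- rseq(21)
    sh <- budmiR:::dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_table(sh), dinuc_table(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 21, 21), substr(s, 21, 21))
  }
})

test_that("a planted cleavage site is called at category 0 with small p", {
  set.seed(33)
  mir <- rseq(21)
  tx <- c(g1 = paste0(rseq(80), revcomp(mir), rseq(60)))
  cleave <- 80 + 21 - 10
  peak_tag <- substr(tx[["g1"]], cleave + 1, cleave + 20)
  bg <- vapply(c(10, 40, 130), function(p)
    substr(tx[["g1"]], p + 1, p + 20), character(1))
  tags <- setNames(c(peak_tag, bg),
                   c("p_x50", paste0("b", 1:3, "_x2")))
  prof <- build_profiles(tags, tx)
  calls <- call_sites(c(m = mir), tx, prof, n_perm = 300, seed = 99)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$cleavage_pos, cleave)
  expect_equal(calls$category, 0L)
  expect_lt(calls$pvalue, 0.05)
  # determinism: same inputs and seed give identical output
  calls2 <- call_sites(c(m = mir), tx, prof, n_perm = 300, seed = 99)
  expect_identical(calls, calls2)
  # a miRNA with no accepted duplex anywhere yields no calls
  none <- call_sites(c(z = rseq(21)), tx, prof, n_perm = 300, seed = 99)
  expect_equal(nrow(none), 0L)
  expect_warning(call_sites(c(m = mir), tx, prof, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("t-plot data mirrors the profile and marks the cleavage position", {
  set.seed(34)
  tx <- c(g = rseq(120))
  prof <- build_profiles(setNames(substr(tx[["g"]], 61, 80), "d_x7"), tx)
  call <- data.frame(transcript_id = "g", cleavage_pos = 60L)
  tp <- tplot(prof$g, call)
  expect_equal(tp$data$count, prof$g$depth)
  expect_equal(tp$data$position, 0:119)
  expect_equal(tp$cleavage_pos, 60L)
  expect_error(tplot(prof$g, data.frame(transcript_id = "other",
                                        cleavage_pos = 3L)),
               "does not reference")
  # unmarked plot data for an empty profile
  prof0 <- build_profiles(setNames(rseq(20), "d_x1"), tx)
  tp0 <- tplot(prof0$g)
  expect_true(all(tp0$data$count == 0))
  expect_true(is.na(tp0$cleavage_pos))
})
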