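small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, library_depth = 4000L, n_known = 4L, n_novel = 4L,
             n_contaminants = 10L, ...)
}

test_that("generated conformant hairpins pass all criteria at evaluation time", {
  set.seed(41)
  for (i in 1:10) {
    h <- make_hairpin()
    expect_true(all(h$criteria_expected))
    support <- data.frame(offset = c(h$mature_offset, h$star_offset),
                          len = c(nchar(h$mature_seq), nchar(h$star_seq)),
                          count = c(h$mature_count, h$star_count))
    call <- evaluate_criteria(h$fold, h$mature_offset, nchar(h$mature_seq),
                              support)
    expect_true(call$accepted)
  }
})

test_that("the MFEI violator's index recomputes below threshold on the emitted sequence", {
  set.seed(42)
  h <- make_hairpin(violate = "mfei_gt_0_8")
  f <- fold(h$precursor)
  expect_lte(f$mfei, 0.8)
  expect_equal(f$mfei, f$amfe / f$gc_percent)
})

test_that("the blunt-overhang violator still has a detectable star", {
  set.seed(43)
  h <- make_hairpin(violate = "overhang_3p_2nt")
  expect_false(is.na(h$star_seq))
  expect_true(h$criteria_expected[["star_detected"]])
  expect_false(h$criteria_expected[["overhang_3p_2nt"]])
})

test_that("simulated libraries are byte-identical at the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_libraries(small_cfg(), d1)
  simulate_libraries(small_cfg(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes the reads
  d3 <- withr::local_tempdir()
  simulate_libraries(small_cfg(seed = 6), d3)
  expect_false(identical(readLines(file.path(d1, "reads_MS.fastq")),
                         readLines(file.path(d3, "reads_MS.fastq"))))
})

test_that("planted counts follow the configured fold changes", {
  d <- withr::local_tempdir()
  sim <- simulate_libraries(sim_config(seed = 7, library_depth = 6000L),
                            d)
  tr <- sim$truth
  fc4 <- tr[is.finite(tr$fold_change) & tr$fold_change == 4, ]
  expect_gt(nrow(fc4), 0)
  ratio <- sum(fc4$count_MS) / sum(fc4$count_MF)
  expect_gt(ratio, 2.5)    # 4 +/- sampling noise
  expect_lt(ratio, 6)
  expect_true(all(tr$count_MF[tr$expected_specificity == "MS_only"] == 0))
  expect_true(all(tr$count_MS[tr$expected_specificity == "MF_only"] == 0))
})

test_that("clean read lengths have their mode within 21-24 nt", {
  d <- withr::local_tempdir()
  sim <- simulate_libraries(small_cfg(seed = 8), d)
  fq <- read_fastq(sim$paths$fastq_ms)
  tf <- trim_and_filter(fq, sim$config$adapter3, sim$config$adapter5)
  mode_len <- as.integer(names(which.max(table(nchar(tf$inserts)))))
  expect_true(mode_len >= 21 && mode_len <= 24)
})

test_that("with zero background every clean tag traces to a planted element", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 9, library_depth = 2000L, n_known = 3L,
                    n_novel = 3L, n_contaminants = 0L,
                    background_fraction = c(rRNA = 0, tRNA = 0, snRNA = 0,
                                            snoRNA = 0, repeat_ = 0,
                                            mrna = 0, random = 0))
  sim <- simulate_libraries(cfg, d)
  fq <- read_fastq(sim$paths$fastq_ms)
  tf <- trim_and_filter(fq, cfg$adapter3, cfg$adapter5)
  planted <- c(sim$truth$mature_seq, sim$truth$star_seq)
  expect_true(all(tf$inserts %in% planted))
})

test_that("degradome simulation peaks at planted cleavage positions", {
  cfg <- small_cfg(seed = 10)
  mirnas <- setNames(vapply(1:4, function(i) rseq(21), character(1)),
                     paste0("m", 1:4))
  tt <- simulate_transcriptome(cfg, mirnas)
  expect_equal(nrow(tt$sites), cfg$n_target_sites)
  # planted site is the exact reverse complement at the recorded window
  s1 <- tt$sites[1, ]
  expect_equal(substr(tt$transcripts[[s1$transcript_id]],
                      s1$site_start + 1, s1$site_end),
               revcomp(mirnas[[s1$mirna_id]]))
  tags <- simulate_degradome(cfg, tt$transcripts, tt$sites)
  prof <- build_profiles(tags, tt$transcripts)
  for (k in seq_len(nrow(tt$sites))) {
    s <- tt$sites[k, ]
    depth <- prof[[s$transcript_id]]$depth
    expect_gte(depth[s$cleavage_pos + 1] / max(cfg$degradome_bg_count, 1), 5)
  }
  # same seed gives identical tags
  tags2 <- simulate_degradome(cfg, tt$transcripts, tt$sites)
  expect_identical(tags, tags2)
  # no background: depth only at planted sites
  cfg0 <- small_cfg(seed = 10, degradome_bg_density = 0)
  tags0 <- simulate_degradome(cfg0, tt$transcripts, tt$sites)
  prof0 <- build_profiles(tags0, tt$transcripts)
  for (ti in names(prof0)) {
    nz <- which(prof0[[ti]]$depth > 0) - 1L
    expect_true(all(nz %in% tt$sites$cleavage_pos[tt$sites$transcript_id == ti]))
  }
})
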