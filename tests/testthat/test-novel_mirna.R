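test_that("tags map to exact genomic loci on both strands", {
  set.seed(12)
  tag <- rseq(21)
  genome <- c(chr1 = paste0(rseq(300), tag, rseq(200), revcomp(tag),
                            rseq(100)))
  loci <- map_tags_genome(tag, genome)
  expect_equal(nrow(loci), 2L)
  expect_setequal(loci$strand, c("+", "-"))
  plus <- loci[loci$strand == "+", ]
  expect_equal(substr(genome[["chr1"]], plus$start + 1, plus$end), tag)
  # absent tag maps nowhere
  expect_equal(nrow(map_tags_genome(rseq(21), genome)), 0L)
  # repeat filter: a tag with too many loci is dropped
  rep_tag <- rseq(21)
  genome2 <- c(chr1 = paste(rep(paste0(rep_tag, "CCC"), 25), collapse = ""))
  expect_equal(nrow(map_tags_genome(rep_tag, genome2, max_loci = 20)), 0L)
})

test_that("candidate windows contain the tag and are truncated at contig edges", {
  set.seed(13)
  genome <- c(tig = rseq(1000))
  locus <- data.frame(chrom = "tig", start = 300L, end = 321L, strand = "+")
  wins <- excise_candidates(locus, genome, flank_up = 100, flank_down = 100)
  expect_equal(nrow(wins), 3L)
  expect_false(any(wins$truncated))
  tag <- substr(genome[["tig"]], 301, 321)
  for (i in 1:3) {
    expect_equal(substr(wins$seq[i], wins$tag_offset[i] + 1,
                        wins$tag_offset[i] + 21), tag)
  }
  # locus near the contig start: upstream window shortened and flagged
  near <- data.frame(chrom = "tig", start = 10L, end = 31L, strand = "+")
  wins2 <- excise_candidates(near, genome, flank_up = 100, flank_down = 100)
  expect_true(wins2$truncated[wins2$window == "upstream"])
  expect_equal(wins2$start[wins2$window == "upstream"], 0L)
  # minus-strand windows carry the tag in sense orientation
  mlocus <- data.frame(chrom = "tig", start = 300L, end = 321L, strand = "-")
  mwins <- excise_candidates(mlocus, genome, flank_up = 80, flank_down = 80)
  expect_equal(substr(mwins$seq[1], mwins$tag_offset[1] + 1,
                      mwins$tag_offset[1] + 21), revcomp(tag))
  expect_error(excise_candidates(
    data.frame(chrom = "nope", start = 1L, end = 22L, strand = "+"), genome),
    "absent")
  # inclusive-coordinate span arithmetic used for reported precursors
  expect_equal(2165863 - 2165738 + 1, 126)
})

test_that("each single-criterion violator fails exactly its criterion", {
  set.seed(14)
  for (v in c("star_detected", "hairpin_duplex_mm_lt3", "overhang_3p_2nt",
              "bulge_ok", "mfei_gt_0_8", "mature_reads_ge5")) {
    h <- make_hairpin(violate = v)
    expect_false(h$criteria_expected[[v]])
    expect_equal(sum(!h$criteria_expected), 1L, info = v)
    # re-evaluate from scratch on the emitted sequence
    support <- data.frame(offset = h$mature_offset,
                          len = nchar(h$mature_seq), count = h$mature_count)
    if (!is.na(h$star_seq))
      support <- rbind(support, data.frame(
        offset = h$star_offset, len = nchar(h$star_seq),
        count = h$star_count))
    call <- evaluate_criteria(fold(h$precursor), h$mature_offset,
                              nchar(h$mature_seq), support)
    expect_false(call$accepted)
    expect_equal(unname(call$criteria), unname(h$criteria_expected), info = v)
  }
})

test_that("three duplex mismatches or four mature reads reject a conformant hairpin", {
  set.seed(15)
  h3 <- make_hairpin(violate = "hairpin_duplex_mm_lt3")
  call <- evaluate_criteria(h3$fold, h3$mature_offset, nchar(h3$mature_seq),
                            data.frame(offset = c(h3$mature_offset, h3$star_offset),
                                       len = c(nchar(h3$mature_seq), nchar(h3$star_seq)),
                                       count = c(8L, 3L)))
  expect_equal(call$duplex$mismatches, 3L)
  expect_false(call$criteria[["hairpin_duplex_mm_lt3"]])
  h4 <- make_hairpin(violate = "mature_reads_ge5")
  expect_equal(h4$mature_count, 4L)
  expect_false(h4$criteria_expected[["mature_reads_ge5"]])
})

test_that("a mature tag spanning the terminal loop is rejected with a reason", {
  set.seed(16)
  h <- make_hairpin()
  f <- h$fold
  # place the "mature" across the loop center
  pt <- pair_table(f$structure)
  loop_mid <- round(f$length / 2)
  call <- evaluate_criteria(f, loop_mid - 5L, 12L,
                            data.frame(offset = loop_mid - 5L, len = 12L,
                                       count = 10L))
  expect_false(call$accepted)
  expect_equal(call$reason, "loop_overlap")
})

test_that("predict_novel recovers planted hairpins and collapses the star arm", {
  set.seed(17)
  h1 <- make_hairpin()
  h2 <- make_hairpin()
  spacer <- strrep("A", 400)
  genome <- c(chr1 = paste0(spacer, h1$precursor, spacer, h2$precursor,
                            spacer))
  mk <- function(h) c(rep(h$mature_seq, 8), rep(h$star_seq, 3))
  tags <- toy_tags(ms = c(mk(h1), mk(h2)), mf = c(h1$mature_seq))
  res <- predict_novel(tags, genome, flank_up = 60, flank_down = 60)
  acc <- res$calls[res$calls$accepted, ]
  expect_setequal(acc$tag_seq, c(h1$mature_seq, h2$mature_seq))
  # the star arms were evaluated but not reported as guides
  expect_true(any(res$calls$reason %in% "star_arm_of_guide" |
                    !res$calls$tag_seq %in% acc$tag_seq))
  expect_true(all(acc$mfei > 0.8))
  expect_true(all(acc$mature_reads >= 5))
  # per-call report has the sequence/structure/marker layout
  rep1 <- format_hairpin_report(res$details[[1]]$call, res$details[[1]]$locus)
  expect_match(rep1[1], "locus chr1:")
  expect_match(rep1[length(rep1)], "\\^")
})
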