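test_that("adapter trimming keeps clean inserts and logs each discard reason", {
  insert21 <- "ACGTACGTACGTACGTACGTC"
  reads <- as_fastq_df(c(
    paste0(insert21, ADAPTER3),                 # kept, insert length 21
    paste0(strrep("A", 20), ADAPTER3),          # polyA
    paste0(rseq(17, seed = 1), ADAPTER3),       # too short
    paste0(rseq(31, seed = 2), ADAPTER3),       # too long
    paste0("ACGTACGTNACGTACGTACGT", ADAPTER3),  # contains N
    rseq(45, seed = 3)))                        # no adapter
  out <- trim_and_filter(reads, ADAPTER3)
  expect_equal(out$inserts, insert21)
  expect_equal(nchar(out$inserts), 21L)
  expect_equal(unname(out$log["polyA"]), 1L)
  expect_equal(unname(out$log["too_short"]), 1L)
  expect_equal(unname(out$log["too_long"]), 1L)
  expect_equal(unname(out$log["has_N"]), 1L)
  expect_equal(unname(out$log["no_adapter"]), 1L)
  expect_equal(unname(out$log["kept"]), 1L)
})

test_that("adapter search tolerates one mismatch and low-quality reads drop first", {
  insert <- "GATTACAGATTACAGATTACA"
  adapter_mut <- ADAPTER3
  substr(adapter_mut, 3, 3) <- ifelse(substr(adapter_mut, 3, 3) == "A", "C", "A")
  reads <- as_fastq_df(c(paste0(insert, adapter_mut),
                         paste0(insert, ADAPTER3)))
  reads$qual[2] <- strrep("#", nchar(reads$seq[2]))  # mean Phred 2
  out <- trim_and_filter(reads, ADAPTER3, min_qual = 20)
  expect_equal(out$inserts, insert)
  expect_equal(unname(out$log["low_quality"]), 1L)
})

test_that("5' adapter is stripped when leading and flagged as contaminant inside", {
  a5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  insert <- "TACGTACGTACGTACGTACGT"
  reads <- c(paste0(a5, insert, ADAPTER3),
             paste0("ACGTACG", a5, "ACGTACGTACGTAC", ADAPTER3))
  out <- trim_and_filter(reads, ADAPTER3, adapter5 = a5)
  expect_equal(out$inserts, insert)
  expect_equal(unname(out$log["adapter5_contaminant"]), 1L)
})

test_that("empty input warns and returns empty output", {
  expect_warning(out <- trim_and_filter(character(0), ADAPTER3))
  expect_length(out$inserts, 0)
})

test_that("malformed FASTQ errors name the record index", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2-bad", "ACGT", "+", "IIII"), f)
  expect_error(read_fastq(f), "record 2")
})

test_that("length law holds after trimming on random input", {
  set.seed(99)
  ins <- vapply(sample(10:40, 200, replace = TRUE), rseq, character(1))
  out <- trim_and_filter(paste0(ins, ADAPTER3), ADAPTER3,
                         min_len = 18, max_len = 30)
  expect_true(all(nchar(out$inserts) >= 18 & nchar(out$inserts) <= 30))
})

test_that("collapse_tags counts multiplicities per library and conserves reads", {
  a <- rseq(21, seed = 10); b <- rseq(21, seed = 11)
  tags <- toy_tags(ms = c(a, a, b), mf = c(b))
  expect_equal(nrow(tags), 2L)
  expect_equal(tags$MS[tags$seq == a], 2L)
  expect_equal(tags$MS[tags$seq == b], 1L)
  expect_equal(tags$MF[tags$seq == b], 1L)
  expect_equal(sum(tags$MS), 3L)   # conservation
  expect_equal(sum(tags$MF), 1L)
  expect_true(all(tags$category == "unannotated"))
  # shared tag appears once with both counts positive
  shared <- toy_tags(ms = c(a), mf = c(a))
  expect_equal(nrow(shared), 1L)
  expect_true(shared$MS == 1L && shared$MF == 1L)
  # empty library gives zero counts, not missing rows
  empty2 <- toy_tags(ms = c(a, b), mf = character(0))
  expect_equal(sum(empty2$MF), 0L)
})

test_that("classification follows the fixed precedence order", {
  rrna_ref <- paste0(rseq(40, seed = 20), "ACGTACGTACGTACGTACGTA", rseq(40))
  tag_rrna_and_genomic <- "ACGTACGTACGTACGTACGTA"
  tag_none <- rseq(22, seed = 21)
  genome <- c(chrA = paste0(rseq(50, seed = 22), tag_rrna_and_genomic,
                            rseq(50)))
  gm <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 150), strand = "+")
  gm$type <- c("gene")
  gm2 <- GenomicRanges::GRanges("chrA", IRanges::IRanges(40, 90), strand = "+")
  gm2$type <- "exon"
  gm <- c(gm, gm2)
  tags <- toy_tags(ms = c(tag_rrna_and_genomic, tag_none), mf = character(0))
  out <- classify_tags(tags, references = list(rRNA = rrna_ref),
                       gene_models = gm, genome = genome)
  # rRNA wins over the exon overlap by precedence
  expect_equal(out$category[out$seq == tag_rrna_and_genomic], "rRNA")
  expect_equal(out$category[out$seq == tag_none], "unannotated")
  expect_error(classify_tags(tags, references = list(junk = rrna_ref)),
               "unknown reference category")
})

test_that("exon/intron categories are strand-aware and summaries conserve counts", {
  set.seed(30)
  gene_seq <- rseq(600)
  genome <- c(chrB = gene_seq)
  gm <- GenomicRanges::GRanges(
    "chrB", IRanges::IRanges(c(1, 1, 401), c(600, 200, 600)),
    strand = "+")
  gm$type <- c("gene", "exon", "exon")
  exon_sense <- substr(gene_seq, 50, 71)
  exon_anti <- revcomp(substr(gene_seq, 100, 121))
  intron_sense <- substr(gene_seq, 250, 271)
  nomatch <- rseq(22)
  tags <- toy_tags(ms = c(exon_sense, exon_anti, intron_sense, nomatch),
                   mf = c(exon_sense))
  out <- classify_tags(tags, gene_models = gm, genome = genome)
  expect_equal(out$category[out$seq == exon_sense], "exon_sense")
  expect_equal(out$category[out$seq == exon_anti], "exon_antisense")
  expect_equal(out$category[out$seq == intron_sense], "intron_sense")
  expect_equal(out$category[out$seq == nomatch], "unannotated")
  s <- tag_summary(out)
  tot <- s[s$category == "Total", ]
  cats <- s[s$category != "Total", ]
  expect_equal(sum(cats$unique_MS), tot$unique_MS)   # conservation, unique
  expect_equal(sum(cats$total_MS), tot$total_MS)     # conservation, totals
  expect_equal(sum(cats$total_MF), tot$total_MF)
})

test_that("classification is deterministic byte for byte", {
  set.seed(31)
  seqs <- vapply(rep(21, 30), rseq, character(1))
  tags1 <- toy_tags(ms = seqs[1:20], mf = seqs[10:30])
  tags2 <- toy_tags(ms = seqs[1:20], mf = seqs[10:30])
  ref <- list(rRNA = seqs[1:3])
  s1 <- tag_summary(classify_tags(tags1, ref))
  s2 <- tag_summary(classify_tags(tags2, ref))
  expect_identical(s1, s2)
})

test_that("library overlap fractions behave on degenerate and hand-counted sets", {
  a <- rseq(21, seed = 40); b <- rseq(21, seed = 41)
  c2 <- rseq(21, seed = 42); d <- rseq(21, seed = 43)
  # identical sets: everything common
  ov <- library_overlap(toy_tags(ms = c(a, b), mf = c(a, b)))
  expect_equal(unname(ov$unique["common"]), 1.0)
  # disjoint 3 + 1 unique tags: specificA = 0.75 of the union
  ov <- library_overlap(toy_tags(ms = c(a, b, c2), mf = c(d)))
  expect_equal(unname(ov$unique["specificA"]), 0.75)
  # counts toy: tag A 5 reads shared in lib1, tag B 5 reads lib1-only
  ov <- library_overlap(toy_tags(ms = c(rep(a, 5), rep(b, 5)),
                                 mf = c(rep(a, 3))))
  expect_equal(unname(ov$per_library_common["MS"]), 0.5)
  # each view's three fractions sum to 1
  expect_equal(sum(ov$unique), 1)
  expect_equal(sum(ov$total), 1)
})

test_that("collapsed-tag FASTA uses count-encoded headers", {
  a <- rseq(21, seed = 50)
  tags <- toy_tags(ms = c(a, a), mf = c(a))
  f <- withr::local_tempfile(fileext = ".fa")
  write_tag_fasta(tags, f)
  expect_match(readLines(f)[1], "^>tag1_x2_y1$")
})
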