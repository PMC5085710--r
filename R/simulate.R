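CRITERIA_NAMES <- c("star_detected", "hairpin_duplex_mm_lt3",
                    "overhang_3p_2nt", "bulge_ok", "mfei_gt_0_8",
                    "mature_reads_ge5")

rand_seq <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic two-library small-RNA study:
#' planted miRNA numbers and abundances, per-miRNA fold changes between the
#' MS and MF libraries (0 = absent in MS, `Inf` = absent in MF), sequencing
#' depth and adapters, background composition, and the degradome
#' peak/background model. Defaults emulate a two-library bud study: 50,000
#' reads per library with a 21-24 nt modal insert length, a miRNA fraction
#' of a few percent, an rRNA/tRNA/snRNA/snoRNA/repeat/mRNA-fragment
#' background, and degradome peaks ten times the background depth.
#'
#' @param seed mandatory RNG seed.
#' @param ... overrides for any default field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  assert_that(!missing(seed), "sim_config(): seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    n_known = 8L, n_novel = 10L,
    fold_changes = c(1, 1, 4, 4, 0.25, 8, 0, Inf),
    base_abundance_meanlog = log(60), base_abundance_sdlog = 0.5,
    library_depth = 50000L, read_len = 40L,
    adapter3 = "TGGAATTCTCGGGTGCCAAGG",
    adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
    ext_len = 15L, loop_len = 8L, spacer_len = 600L,
    star_lambda = 2,
    n_ref_per_category = 12L, ref_len = 150L,
    background_fraction = c(rRNA = 0.10, tRNA = 0.05, snRNA = 0.01,
                            snoRNA = 0.01, repeat_ = 0.07, mrna = 0.06,
                            random = 0.60),
    n_contaminants = 40L,
    n_transcripts = 8L, transcript_len = 400L, n_target_sites = 8L,
    degradome_peak = 20, degradome_bg_count = 2L,
    degradome_bg_density = 0.05)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  assert_that(length(bad) == 0L,
              paste0("sim_config(): unknown field(s): ", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Generate one synthetic pre-miRNA hairpin with known criterion status
#'
#' Builds a precursor whose five-criterion evaluation is known by
#' construction: a perfect inverted-repeat stem (flank extension + mature)
#' around a non-pairing loop, with the miRNA* defined by the 2-nt 3'
#' Dicer offset. `violate` engineers a failure of exactly one criterion:
#' \itemize{
#' \item `star_detected`: no miRNA* tag is emitted;
#' \item `hairpin_duplex_mm_lt3`: three non-pairable 1x1 internal loops are
#'   planted in the duplex;
#' \item `overhang_3p_2nt`: the emitted miRNA* is blunt-ended;
#' \item `bulge_ok`: a 2-nt asymmetric bulge is inserted on the star strand;
#' \item `mfei_gt_0_8`: unpaired C runs flank the hairpin, raising GC
#'   content without adding pairing energy;
#' \item `mature_reads_ge5`: the mature read count is set to 4.
#' }
#' Every hairpin is verified at generation time by folding it with the
#' default engine and running [evaluate_criteria()]; construction retries
#' with fresh sequences until the realized criteria match the intended
#' pattern.
#'
#' @param conformant if `TRUE` (and `violate` is `NULL`) all criteria hold.
#' @param violate name of the single criterion to break, or `NULL`.
#' @param mature_len,ext_len,loop_len geometry in nt.
#' @param mature_count,star_count planted read counts.
#' @param max_attempts construction retries before erroring.
#' @return list with `precursor`, `fold`, `mature_seq`, `star_seq` (`NA`
#'   when no star is emitted), `mature_offset`, `star_offset` (1-based),
#'   `mature_count`, `star_count`, `criteria_expected`, `violate`.
#' @export
make_hairpin <- function(conformant = TRUE, violate = NULL, mature_len = 21L,
                         ext_len = 15L, loop_len = 8L, mature_count = 8L,
                         star_count = 3L, max_attempts = 100L) {
  if (!is.null(violate)) {
    violate <- match.arg(violate, CRITERIA_NAMES)
    conformant <- FALSE
  }
  E <- ext_len; M <- mature_len; L <- loop_len
  stem_probs <- c(A = .22, C = .28, G = .28, T = .22)
  for (att in seq_len(max_attempts)) {
    mature <- rand_seq(M, stem_probs)
    ext5 <- rand_seq(E, stem_probs)
    loop <- rand_seq(L, c(A = .5, C = .5))
    pre <- paste0(ext5, mature, loop, revcomp(mature), revcomp(ext5))
    m_off <- E + 1L
    R0 <- E + M + L   # offset of the reverse-complement mature block
    if (identical(violate, "hairpin_duplex_mm_lt3")) {
      mb <- strsplit(mature, "")[[1]]
      cand <- which(mb %in% c("A", "C"))
      cand <- cand[cand >= 4L & cand <= M - 3L]
      picks <- integer(0)
      for (ci in cand) {
        if (all(abs(ci - picks) >= 3L)) picks <- c(picks, ci)
        if (length(picks) == 3L) break
      }
      if (length(picks) < 3L) next
      for (mpos in picks) {
        j <- R0 + (M - mpos + 1L)       # partner position in the stem
        substr(pre, j, j) <- mb[mpos]   # same base: no longer pairable
      }
    } else if (identical(violate, "bulge_ok")) {
      j <- R0 + (M - 10L)               # between partners of mature 11 and 10
      pre <- paste0(substr(pre, 1L, j), rand_seq(2L, c(A = .5, C = .5)),
                    substr(pre, j + 1L, nchar(pre)))
    } else if (identical(violate, "mfei_gt_0_8")) {
      # unpaired C runs raise GC% without adding pairs, diluting MFEI;
      # C pairs only G, and every G is consumed inside the stem
      pre <- paste0(strrep("C", 35L), pre, strrep("C", 35L))
      m_off <- m_off + 35L
    }
    f <- fold(pre)
    pt <- pair_table(f$structure)
    ds <- duplex_stats(pt, m_off, m_off + M - 1L)
    if (is.null(ds)) next
    span <- sort(c(pt[ds$last], pt[ds$first]))
    star_span <- if (identical(violate, "overhang_3p_2nt")) span else span + 2L
    if (star_span[2] > nchar(pre)) next
    star_seq <- substr(pre, star_span[1], star_span[2])
    emit_star <- !identical(violate, "star_detected")
    mc <- if (identical(violate, "mature_reads_ge5")) 4L else mature_count
    support <- data.frame(offset = m_off, len = M, count = mc)
    if (emit_star)
      support <- rbind(support,
                       data.frame(offset = star_span[1],
                                  len = diff(star_span) + 1L,
                                  count = star_count))
    call <- evaluate_criteria(f, m_off, M, support)
    expected <- setNames(rep(TRUE, length(CRITERIA_NAMES)), CRITERIA_NAMES)
    if (!is.null(violate)) expected[violate] <- FALSE
    if (!is.na(call$reason)) next
    if (!identical(unname(call$criteria[CRITERIA_NAMES]), unname(expected)))
      next
    return(list(precursor = pre, fold = f,
                mature_seq = substr(pre, m_off, m_off + M - 1L),
                star_seq = if (emit_star) star_seq else NA_character_,
                mature_offset = m_off, star_offset = star_span[1],
                mature_count = mc,
                star_count = if (emit_star) star_count else 0L,
                criteria_expected = expected, violate = violate))
  }
  stop("make_hairpin(): construction failed after ", max_attempts,
       " attempts (re-seed)", call. = FALSE)
}

## expected fold-change class from a planted MS:MF ratio
fc_class <- function(fc) {
  if (fc == 0 || is.infinite(fc)) return("high")
  m <- max(fc, 1 / fc)
  if (m > 2) "high" else if (m >= 1.2) "mid" else "low"
}

#' Simulate a complete two-library small-RNA study with planted truth
#'
#' Emits everything the pipeline consumes: two adapter-ligated FASTQ
#' libraries (MS and MF) containing planted known-miRNA reads,
#' novel-miRNA/miRNA* reads from genome-planted hairpins, category-labelled
#' ncRNA/repeat/mRNA background, random unannotated tags and a sprinkling
#' of contaminants exercising every discard reason; a genome FASTA carrying
#' the novel hairpins separated by non-pairing poly-A spacers plus a
#' gene-bearing chromosome; a mature-miRNA reference; per-category ncRNA
#' reference sets; GFF3 gene models; and a truth table recording every
#' planted element with its per-library counts and expected
#' differential-expression class.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths), `truth` (per-miRNA truth
#'   `data.frame`), `genome`, `mature_ref`, `references` (in-memory copies)
#'   and `config`.
#' @export
simulate_libraries <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  nK <- config$n_known; nV <- config$n_novel
  n_mir <- nK + nV
  fcs <- rep_len(config$fold_changes, n_mir)

  # known miRNAs: free mature sequences listed in the reference
  known_len <- sample(c(21L, 22L, 23L, 24L), nK, replace = TRUE,
                      prob = c(.35, .15, .1, .4))
  known_seq <- vapply(known_len, rand_seq, character(1))
  arm <- rep_len(c("", "-5p", "-3p"), nK)
  known_id <- sprintf("ghr-miR%d%s", 100 + seq_len(nK), arm)

  # novel miRNAs: conformant hairpins planted on chr1
  hairpins <- lapply(seq_len(nV), function(i)
    make_hairpin(mature_len = sample(c(21L, 22L, 24L), 1,
                                     prob = c(.5, .2, .3)),
                 ext_len = config$ext_len, loop_len = config$loop_len))
  spacer <- strrep("A", config$spacer_len)
  chr1 <- spacer
  pre_start <- integer(nV)
  for (i in seq_len(nV)) {
    pre_start[i] <- nchar(chr1)            # 0-based precursor start
    chr1 <- paste0(chr1, hairpins[[i]]$precursor, spacer)
  }
  # chr2: random sequence hosting the gene models for exon/intron classes
  chr2 <- rand_seq(3000L)
  genome <- c(chr1 = chr1, chr2 = chr2)

  # gene models on chr2 (1-based GFF coordinates)
  gene_rows <- data.frame(
    type = c("gene", "exon", "exon", "gene", "exon", "exon"),
    start = c(201L, 201L, 1001L, 1701L, 1701L, 2301L),
    end = c(1400L, 600L, 1400L, 2600L, 2000L, 2600L),
    strand = c("+", "+", "+", "-", "-", "-"),
    ID = c("gene1", "gene1.e1", "gene1.e2", "gene2", "gene2.e1", "gene2.e2"))
  gm <- GenomicRanges::GRanges("chr2",
                               IRanges::IRanges(gene_rows$start, gene_rows$end),
                               strand = gene_rows$strand)
  gm$type <- gene_rows$type
  gm$ID <- gene_rows$ID

  # ncRNA / repeat reference sets (synthetic, category-labelled)
  ref_cats <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")
  references <- lapply(ref_cats, function(cc) {
    s <- vapply(seq_len(config$n_ref_per_category), function(i)
      rand_seq(config$ref_len), character(1))
    setNames(s, sprintf("%s_%d", cc, seq_along(s)))
  })
  names(references) <- ref_cats

  # planted per-library counts
  base <- rlnorm(n_mir, config$base_abundance_meanlog,
                 config$base_abundance_sdlog)
  ms_mean <- ifelse(is.infinite(fcs), base, base * fcs)
  mf_mean <- ifelse(is.infinite(fcs), 0, base)
  cnt_ms <- rpois(n_mir, ms_mean)
  cnt_mf <- rpois(n_mir, mf_mean)
  star_ms <- c(rep(0L, nK), rpois(nV, config$star_lambda) + 1L)
  star_mf <- c(rep(0L, nK), rpois(nV, config$star_lambda) + 1L)

  mature_seqs <- c(known_seq, vapply(hairpins, `[[`, character(1), "mature_seq"))
  star_seqs <- c(rep(NA_character_, nK),
                 vapply(hairpins, `[[`, character(1), "star_seq"))
  truth <- data.frame(
    mirna_id = c(known_id, sprintf("novel_mir_%d", seq_len(nV))),
    type = rep(c("known", "novel"), c(nK, nV)),
    mature_seq = mature_seqs, star_seq = star_seqs,
    chrom = rep(c(NA, "chr1"), c(nK, nV)),
    precursor_start = c(rep(NA_integer_, nK), pre_start),
    precursor_end = c(rep(NA_integer_, nK),
                      pre_start + vapply(hairpins, function(h)
                        nchar(h$precursor), integer(1))),
    mature_start = c(rep(NA_integer_, nK),
                     pre_start + vapply(hairpins, `[[`, integer(1),
                                        "mature_offset") - 1L),
    count_MS = cnt_ms, count_MF = cnt_mf,
    star_MS = star_ms, star_MF = star_mf,
    fold_change = fcs,
    expected_class = vapply(fcs, fc_class, character(1)),
    expected_specificity = ifelse(fcs == 0, "MF_only",
                                  ifelse(is.infinite(fcs), "MS_only",
                                         "common")),
    stringsAsFactors = FALSE)

  # background tags: category-labelled fragments plus random noise
  bg_total <- config$library_depth -
    (sum(cnt_ms) + sum(cnt_mf) + sum(star_ms) + sum(star_mf)) / 2
  frac <- config$background_fraction
  tag_len <- function(n) sample(21:24, n, replace = TRUE,
                                prob = c(.2, .15, .15, .5))
  draw_fragment <- function(src) {
    w <- tag_len(1L)
    s <- sample(length(src), 1L)
    start <- sample(max(1L, nchar(src[s]) - w), 1L)
    substr(src[s], start, start + w - 1L)
  }
  bg_tags <- character(0); bg_mean <- numeric(0)
  for (cc in ref_cats) {
    n_cc <- ceiling(bg_total * frac[[sub("repeat", "repeat_", cc)]] / 4)
    if (n_cc <= 0) next
    tg <- vapply(seq_len(n_cc), function(i) {
      t <- draw_fragment(references[[cc]])
      if (runif(1) < 0.3) revcomp(t) else t
    }, character(1))
    bg_tags <- c(bg_tags, tg); bg_mean <- c(bg_mean, rep(4, n_cc))
  }
  # mRNA fragments from the chr2 gene regions (sense and antisense)
  n_mrna <- ceiling(bg_total * frac[["mrna"]] / 4)
  regions <- gene_rows[, c("start", "end", "strand")]
  mrna_tags <- vapply(seq_len(n_mrna), function(i) {
    r <- regions[sample(nrow(regions), 1L), ]
    w <- tag_len(1L)
    st <- sample(r$start:(r$end - w), 1L)
    t <- substr(chr2, st, st + w - 1L)
    if (r$strand == "-") t <- revcomp(t)
    if (runif(1) < 0.4) t <- revcomp(t)   # antisense fraction
    t
  }, character(1))
  bg_tags <- c(bg_tags, mrna_tags); bg_mean <- c(bg_mean, rep(4, n_mrna))
  # random unannotated tags, mostly count 1
  n_rand <- ceiling(bg_total * frac[["random"]] / 1.4)
  rand_tags <- vapply(tag_len(n_rand), rand_seq, character(1))
  bg_tags <- c(bg_tags, rand_tags)
  bg_mean <- c(bg_mean, rep(1.4, n_rand))
  bg_ms <- rpois(length(bg_tags), bg_mean)
  bg_mf <- rpois(length(bg_tags), bg_mean)

  build_reads <- function(lib) {
    counts <- if (lib == "MS") c(cnt_ms, star_ms, bg_ms)
              else c(cnt_mf, star_mf, bg_mf)
    seqs <- c(mature_seqs, star_seqs, bg_tags)
    ok <- !is.na(seqs) & counts > 0
    inserts <- rep(seqs[ok], counts[ok])
    nb <- config$n_contaminants
    contaminants <- c(
      vapply(seq_len(nb), function(i) rand_seq(config$read_len), character(1)),     # no adapter
      rep(strrep("A", 22L), nb),                                                    # polyA insert
      vapply(seq_len(nb), function(i) rand_seq(16L), character(1)),                 # too short
      vapply(seq_len(nb), function(i) {                                             # N-containing
        s <- rand_seq(22L); substr(s, 11L, 11L) <- "N"; s
      }, character(1)))
    inserts <- c(inserts, contaminants)
    reads <- substr(paste0(inserts, config$adapter3,
                           strrep("A", config$read_len)), 1L, config$read_len)
    # low-quality reads (discarded on mean Phred)
    lowq <- vapply(seq_len(nb), function(i) rand_seq(config$read_len),
                   character(1))
    reads <- c(reads, lowq)
    quals <- c(rep(strrep("I", config$read_len), length(reads) - nb),
               rep(strrep("#", config$read_len), nb))
    ord <- sample(length(reads))
    list(seq = reads[ord], qual = quals[ord])
  }
  paths <- list(
    fastq_ms = file.path(dir, "reads_MS.fastq"),
    fastq_mf = file.path(dir, "reads_MF.fastq"),
    genome = file.path(dir, "genome.fa"),
    gene_models = file.path(dir, "genes.gff3"),
    mature_ref = file.path(dir, "mature_ref.fa"),
    truth = file.path(dir, "truth_mirna.tsv"),
    config = file.path(dir, "sim_config.json"))
  for (cc in ref_cats)
    paths[[paste0("ref_", cc)]] <- file.path(dir, paste0("ref_", cc, ".fa"))
  for (lib in c("MS", "MF")) {
    r <- build_reads(lib)
    writeLines(paste0("@r", seq_along(r$seq), "\n", r$seq, "\n+\n", r$qual),
               paths[[if (lib == "MS") "fastq_ms" else "fastq_mf"]])
  }
  write_fasta_seqs(genome, paths$genome)
  rtracklayer::export(gm, paths$gene_models, format = "gff3")
  # mature reference: planted known miRNAs plus unexpressed decoys
  decoys <- setNames(vapply(1:5, function(i) rand_seq(21L), character(1)),
                     sprintf("ghr-miR%d", 900 + 1:5))
  write_fasta_seqs(c(setNames(known_seq, known_id), decoys), paths$mature_ref)
  for (cc in ref_cats) write_fasta_seqs(references[[cc]], paths[[paste0("ref_", cc)]])
  write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  list(paths = paths, truth = truth, genome = genome,
       mature_ref = c(setNames(known_seq, known_id), decoys),
       references = references, config = config)
}

#' Simulate a transcriptome with planted miRNA target sites
#'
#' Random transcripts with perfect-complement sites of the given miRNAs
#' planted at recorded positions; the predicted cleavage position (opposite
#' miRNA position 10) is part of the truth.
#'
#' @param config a [sim_config()].
#' @param mirnas named character vector of mature miRNA sequences.
#' @return list with `transcripts` (named character vector) and `sites`
#'   (truth `data.frame`: `mirna_id`, `transcript_id`, `site_start`,
#'   `site_end` 0-based half-open, `cleavage_pos`).
#' @export
simulate_transcriptome <- function(config, mirnas) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  nT <- config$n_transcripts
  len <- config$transcript_len
  tx <- setNames(vapply(seq_len(nT), function(i) rand_seq(len), character(1)),
                 sprintf("Cotton_D_gene_%05d", seq_len(nT)))
  n_sites <- min(config$n_target_sites, nT * 2L)
  sites <- list()
  slot_used <- list()
  for (k in seq_len(n_sites)) {
    mi <- names(mirnas)[(k - 1L) %% length(mirnas) + 1L]
    ti <- names(tx)[(k - 1L) %% nT + 1L]
    m <- nchar(mirnas[[mi]])
    # two non-overlapping slots per transcript, away from both ends
    slot <- length(slot_used[[ti]] %||% integer(0)) + 1L
    start0 <- if (slot == 1L) 60L else 220L
    slot_used[[ti]] <- c(slot_used[[ti]] %||% integer(0), slot)
    site <- revcomp(mirnas[[mi]])
    substr(tx[[ti]], start0 + 1L, start0 + m) <- site
    sites[[k]] <- data.frame(mirna_id = mi, transcript_id = ti,
                             site_start = start0, site_end = start0 + m,
                             cleavage_pos = start0 + m - 10L,
                             stringsAsFactors = FALSE)
  }
  list(transcripts = tx, sites = do.call(rbind, sites))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate degradome tags over a transcriptome
#'
#' At every planted cleavage site, emits a 20-nt tag whose 5' end sits at
#' the cleavage position with a Poisson(`degradome_peak`) count; background
#' tags start at uniformly sampled positions with count
#' `degradome_bg_count`, at `degradome_bg_density` sites per nt.
#'
#' @param config a [sim_config()].
#' @param transcripts named character vector.
#' @param sites truth `data.frame` from [simulate_transcriptome()].
#' @return named character vector of tags with count-encoded names
#'   (`dtag{i}_x{count}`).
#' @export
simulate_degradome <- function(config, transcripts, sites) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  tags <- character(0); counts <- integer(0)
  for (k in seq_len(nrow(sites))) {
    tr <- transcripts[[sites$transcript_id[k]]]
    pos <- sites$cleavage_pos[k]
    tags <- c(tags, substr(tr, pos + 1L, pos + 20L))
    counts <- c(counts, rpois(1L, config$degradome_peak))
  }
  for (ti in names(transcripts)) {
    tr <- transcripts[[ti]]
    n_bg <- round((nchar(tr) - 20L) * config$degradome_bg_density)
    if (n_bg <= 0) next
    pos <- sample(nchar(tr) - 20L, n_bg)
    tags <- c(tags, substr(rep(tr, n_bg), pos + 1L, pos + 20L))
    counts <- c(counts, rep(config$degradome_bg_count, n_bg))
  }
  ok <- counts > 0 & nchar(tags) >= 18L
  setNames(tags[ok], sprintf("dtag%d_x%d", seq_len(sum(ok)), counts[ok]))
}
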