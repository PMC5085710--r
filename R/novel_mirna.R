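#' Excise candidate precursor windows around a genomic tag locus
#'
#' For one exact tag locus, emits up to three candidate precursor windows:
#' tag plus upstream flank, tag plus downstream flank, and tag centered
#' (half flanks on both sides). Windows truncated at a chromosome edge are
#' shortened and flagged. Sequences are strand-adjusted, so the tag always
#' appears in sense orientation at `tag_offset` (0-based within the window).
#'
#' @param locus one-row `data.frame` (`chrom`, `start`, `end`, `strand`;
#'   0-based half-open) as produced by [map_tags_genome()].
#' @param genome named character vector of chromosome sequences, or FASTA
#'   path.
#' @param flank_up,flank_down flank sizes in nt (defaults 250).
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`, `window`
#'   (label), `truncated`, `seq`, `tag_offset`, `tag_len`.
#' @export
excise_candidates <- function(locus, genome, flank_up = 250L,
                              flank_down = 250L) {
  assert_that(flank_up >= 20L && flank_down >= 20L,
              "excise_candidates(): flanks must be >= 20 nt")
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta_seqs(genome)
  assert_that(locus$chrom %in% names(genome),
              sprintf("excise_candidates(): chromosome '%s' absent from genome", locus$chrom))
  chr_seq <- genome[[locus$chrom]]
  chr_len <- nchar(chr_seq)
  # window definitions in genomic coordinates; "up/down" are genomic here
  # and strand-adjusted on extraction
  defs <- list(
    upstream = c(locus$start - flank_up, locus$end),
    downstream = c(locus$start, locus$end + flank_down),
    centered = c(locus$start - flank_up %/% 2L, locus$end + flank_down %/% 2L))
  out <- do.call(rbind, lapply(names(defs), function(w) {
    s <- defs[[w]][1]; e <- defs[[w]][2]
    truncated <- s < 0L || e > chr_len
    s <- max(0L, s); e <- min(chr_len, e)
    seq <- substr(chr_seq, s + 1L, e)
    if (locus$strand == "-") seq <- revcomp(seq)
    tag_offset <- if (locus$strand == "+") locus$start - s else e - locus$end
    data.frame(chrom = locus$chrom, start = s, end = e,
               strand = locus$strand, window = w, truncated = truncated,
               seq = seq, tag_offset = tag_offset,
               tag_len = locus$end - locus$start, stringsAsFactors = FALSE)
  }))
  out
}

## mismatch / bulge statistics of the miRNA:miRNA* duplex, from the pair
## table restricted to the mature span [m1, m2] (1-based inclusive).
## A mismatch is an unpaired mature base whose opposite-strand partner
## region is also unpaired (internal loops count once per mature base);
## an asymmetric bulge is a run of unpaired bases on one strand only.
duplex_stats <- function(pt, m1, m2) {
  paired <- intersect(m1:m2, which(pt > 0))
  if (length(paired) < 2L) return(NULL)
  mism <- 0L; bulges <- 0L; bulged_bases <- 0L
  for (k in seq_len(length(paired) - 1L)) {
    i <- paired[k]; j <- paired[k + 1L]
    gap_m <- j - i - 1L
    gap_s <- abs(pt[i] - pt[j]) - 1L
    if (gap_m == 0L && gap_s == 0L) next
    mism <- mism + min(gap_m, gap_s)
    asym <- abs(gap_m - gap_s)
    if (asym > 0L) {
      bulges <- bulges + 1L
      bulged_bases <- bulged_bases + asym
    }
  }
  list(mismatches = mism, bulges = bulges, bulged_bases = bulged_bases,
       first = paired[1L], last = paired[length(paired)])
}

## terminal-loop spans of a structure: maximal unpaired runs directly
## enclosed by a pair
hairpin_loops <- function(pt) {
  n <- length(pt)
  loops <- list()
  i <- 1L
  while (i <= n) {
    if (pt[i] == 0L) {
      j <- i
      while (j < n && pt[j + 1L] == 0L) j <- j + 1L
      if (i > 1L && j < n && pt[i - 1L] == j + 1L)
        loops[[length(loops) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  loops
}

#' Evaluate the five novel-miRNA criteria on a folded candidate window
#'
#' Applies the standard plant-miRNA annotation criteria to one folded
#' precursor window given the sequenced-tag support inside it:
#' \itemize{
#' \item `star_detected`: some sequenced tag maps (with up to `star_wobble`
#'   nt end wobble) to the miRNA* region predicted from the structure (the
#'   positions paired to the mature span, offset by the 2-nt 3' Dicer
#'   geometry);
#' \item `hairpin_duplex_mm_lt3`: fewer than 3 mismatched bases in the
#'   miRNA/miRNA* duplex;
#' \item `overhang_3p_2nt`: the duplex shows 2-nt 3' overhangs on both
#'   strands, judged on the observed miRNA* tag when one is sequenced and on
#'   the structure-predicted star otherwise;
#' \item `bulge_ok`: at most one asymmetric bulge and fewer than 2 bulged
#'   bases in the duplex;
#' \item `mfei_gt_0_8`: precursor MFEI above `mfei_min`;
#' \item `mature_reads_ge5`: at least `min_mature_reads` reads support the
#'   mature tag.
#' }
#' A candidate whose mature span overlaps a terminal loop is rejected
#' outright with reason `"loop_overlap"`.
#'
#' @param fold a `precursor_fold` of the window (from [fold()]).
#' @param mature_start 1-based start of the mature tag within the window.
#' @param mature_len mature tag length.
#' @param tag_support `data.frame` of sequenced tags inside the window:
#'   columns `offset` (1-based start), `len`, `count`.
#' @param min_mature_reads,mfei_min,star_wobble criterion parameters
#'   (defaults 5 reads, 0.8, 2 nt).
#' @return object of class `novel_mirna_call`: criteria booleans, `accepted`
#'   (their conjunction), mature/star sequences and read counts, and a
#'   rejection `reason` when structurally invalid.
#' @export
evaluate_criteria <- function(fold, mature_start, mature_len, tag_support,
                              min_mature_reads = 5L, mfei_min = 0.8,
                              star_wobble = 2L) {
  pt <- pair_table(fold$structure)
  n <- fold$length
  m1 <- mature_start
  m2 <- mature_start + mature_len - 1L
  assert_that(m1 >= 1L && m2 <= n, "evaluate_criteria(): mature outside window")
  reject <- function(reason) {
    structure(list(precursor = fold, mature_start = m1,
                   mature_seq = substr(fold$seq, m1, m2),
                   star_seq = NA_character_, mature_reads = 0L,
                   star_reads = 0L,
                   criteria = c(star_detected = FALSE,
                                hairpin_duplex_mm_lt3 = FALSE,
                                overhang_3p_2nt = FALSE, bulge_ok = FALSE,
                                mfei_gt_0_8 = FALSE, mature_reads_ge5 = FALSE),
                   accepted = FALSE, reason = reason),
              class = "novel_mirna_call")
  }
  for (lp in hairpin_loops(pt))
    if (m1 <= lp[2] && m2 >= lp[1]) return(reject("loop_overlap"))
  ds <- duplex_stats(pt, m1, m2)
  if (is.null(ds)) return(reject("unpaired_mature"))
  # predicted star: partners of the mature span, shifted by the 2-nt 3'
  # Dicer offset (same formula for 5'- and 3'-arm matures)
  star_pred <- sort(c(pt[ds$last] + 2L, pt[ds$first] + 2L))
  star_pred[1] <- max(1L, star_pred[1]); star_pred[2] <- min(n, star_pred[2])
  mature_rows <- tag_support$offset == m1 & tag_support$len == mature_len
  mature_reads <- sum(tag_support$count[mature_rows])
  cand <- !mature_rows &
    abs(tag_support$offset - star_pred[1]) <= star_wobble &
    abs(tag_support$offset + tag_support$len - 1L - star_pred[2]) <= star_wobble
  star_detected <- any(cand)
  if (star_detected) {
    best <- which(cand)[which.max(tag_support$count[cand])]
    s1 <- tag_support$offset[best]
    s2 <- s1 + tag_support$len[best] - 1L
    star_reads <- sum(tag_support$count[cand])
    star_seq <- substr(fold$seq, s1, s2)
  } else {
    s1 <- star_pred[1]; s2 <- star_pred[2]
    star_reads <- 0L
    star_seq <- NA_character_
  }
  # 2-nt 3' overhang on both strands, measured on the (observed or
  # predicted) star span: star 3' end vs the partner of the mature 5' end,
  # and mature 3' end vs the partner of the star 5' end
  s_paired <- intersect(s1:s2, which(pt > 0))
  overhang <- if (length(s_paired) == 0L) FALSE else {
    o1 <- s2 - pt[ds$first]
    o2 <- m2 - pt[s_paired[1L]]
    (o1 == 2L) && (o2 == 2L)
  }
  criteria <- c(
    star_detected = star_detected,
    hairpin_duplex_mm_lt3 = ds$mismatches < 3L,
    overhang_3p_2nt = overhang,
    bulge_ok = ds$bulges <= 1L && ds$bulged_bases < 2L,
    mfei_gt_0_8 = fold$mfei > mfei_min,
    mature_reads_ge5 = mature_reads >= min_mature_reads)
  structure(list(precursor = fold, mature_start = m1,
                 mature_seq = substr(fold$seq, m1, m2), star_seq = star_seq,
                 star_start = s1, mature_reads = mature_reads,
                 star_reads = star_reads, criteria = criteria,
                 accepted = all(criteria), reason = NA_character_,
                 duplex = ds[c("mismatches", "bulges", "bulged_bases")]),
            class = "novel_mirna_call")
}

#' @export
print.novel_mirna_call <- function(x, ...) {
  cat(sprintf("<novel_mirna_call> %s (%s)\n",
              if (x$accepted) "ACCEPTED" else "rejected",
              if (!is.na(x$reason)) x$reason else
                paste(names(x$criteria)[!x$criteria], collapse = ", ")))
  cat(format_hairpin_report(x), sep = "\n")
  invisible(x)
}

#' Plain-text hairpin report for one candidate call
#'
#' Sequence, dot-bracket structure, mature/star underlining and the energy
#' statistics, in the conventional precursor-report layout.
#'
#' @param call a `novel_mirna_call`.
#' @param locus optional one-row locus `data.frame` for the header.
#' @return character vector of report lines.
#' @export
format_hairpin_report <- function(call, locus = NULL) {
  f <- call$precursor
  mark <- rep(" ", f$length)
  m2 <- call$mature_start + nchar(call$mature_seq) - 1L
  mark[call$mature_start:m2] <- "^"
  if (!is.na(call$star_seq) && !is.null(call$star_start)) {
    s2 <- call$star_start + nchar(call$star_seq) - 1L
    mark[call$star_start:s2] <- "*"
  }
  hdr <- if (!is.null(locus))
    sprintf("# locus %s:%d-%d(%s)", locus$chrom, locus$start + 1L,
            locus$end, locus$strand) else "# candidate precursor"
  c(hdr,
    sprintf("# length %d nt  MFE %.2f kcal/mol  AMFE %.2f  GC %.1f%%  MFEI %.3f",
            f$length, f$mfe, f$amfe, f$gc_percent, f$mfei),
    sprintf("# mature reads %d  star reads %d", call$mature_reads,
            call$star_reads),
    f$seq, f$structure, paste(mark, collapse = ""))
}

#' Predict novel miRNAs from residual tags
#'
#' Full novel-miRNA operation: maps residual (unannotated) tags to exact
#' genomic loci, excises candidate precursor windows around each locus,
#' folds them, evaluates the five annotation criteria with the mapped-tag
#' support, and collapses overlapping accepted windows of one locus to the
#' window with the best (most negative) MFE. Each locus of a multi-locus
#' tag is evaluated independently. When both arms of one precursor pass the
#' criteria (the miRNA* itself has five or more reads), only the
#' more-abundant arm is reported as the miRNA (guide-strand convention);
#' the other arm is marked `star_arm_of_guide`.
#'
#' @param tags a `tag_table` of residual tags (e.g. `match_known()$residual`).
#' @param genome named character vector or FASTA path.
#' @param flank_up,flank_down window flank sizes (default 250 nt).
#' @param max_loci repeat-filter threshold for [map_tags_genome()].
#' @param engine folding engine, see [fold()].
#' @param min_mature_reads,mfei_min criterion parameters.
#' @return list of class `novel_mirna_result`: `calls` (`data.frame`, one
#'   row per evaluated locus with per-criterion columns and per-library
#'   mature counts) and `details` (list of `novel_mirna_call` objects for
#'   accepted calls).
#' @export
predict_novel <- function(tags, genome, flank_up = 250L, flank_down = 250L,
                          max_loci = 20L, engine = "nussinov",
                          min_mature_reads = 5L, mfei_min = 0.8) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta_seqs(genome)
  libs <- count_cols(tags)
  total_counts <- rowSums(as.matrix(tags[, libs, drop = FALSE]))
  loci <- map_tags_genome(tags$seq, genome, max_loci = max_loci)
  rows <- list(); details <- list()
  for (li in seq_len(nrow(loci))) {
    locus <- loci[li, , drop = FALSE]
    wins <- excise_candidates(locus, genome, flank_up, flank_down)
    best <- NULL; best_win <- NULL
    for (wi in seq_len(nrow(wins))) {
      w <- wins[wi, , drop = FALSE]
      f <- fold(w$seq, engine = engine)
      # support: every mapped tag locus inside this window, same strand
      sup <- loci[loci$chrom == w$chrom & loci$strand == w$strand &
                    loci$start >= w$start & loci$end <= w$end, , drop = FALSE]
      if (nrow(sup)) {
        off <- if (w$strand == "+") sup$start - w$start + 1L
               else w$end - sup$end + 1L
        support <- data.frame(offset = off, len = sup$end - sup$start,
                              count = total_counts[match(sup$seq, tags$seq)])
      } else {
        support <- data.frame(offset = integer(0), len = integer(0),
                              count = numeric(0))
      }
      call <- evaluate_criteria(f, w$tag_offset + 1L, w$tag_len, support,
                                min_mature_reads = min_mature_reads,
                                mfei_min = mfei_min)
      if (is.null(best) ||
          (call$accepted && (!best$accepted || f$mfe < best$precursor$mfe)) ||
          (!best$accepted && !call$accepted && f$mfe < best$precursor$mfe)) {
        best <- call; best_win <- w
      }
    }
    if (is.null(best)) next
    i <- match(locus$seq, tags$seq)
    row <- data.frame(tag_seq = locus$seq, chrom = locus$chrom,
                      start = locus$start, end = locus$end,
                      strand = locus$strand,
                      precursor_start = best_win$start,
                      precursor_end = best_win$end,
                      mfe = best$precursor$mfe, amfe = best$precursor$amfe,
                      mfei = best$precursor$mfei,
                      mature_reads = best$mature_reads,
                      star_reads = best$star_reads,
                      star_seq = best$star_seq,
                      reason = best$reason, stringsAsFactors = FALSE)
    for (cr in names(best$criteria)) row[[cr]] <- unname(best$criteria[cr])
    row$accepted <- best$accepted
    for (nm in libs) row[[nm]] <- tags[[nm]][i]
    rows[[length(rows) + 1L]] <- row
    if (best$accepted) {
      details[[length(details) + 1L]] <-
        list(call = best, locus = locus, window = best_win)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag_seq = character(0), accepted = logical(0))
  # guide-strand collapse: when two accepted calls share an overlapping
  # precursor (a mature/star pair each passing the criteria), report only
  # the more-abundant arm as the miRNA
  if (nrow(calls) > 1L && any(calls$accepted)) {
    acc <- which(calls$accepted)
    reads <- calls$mature_reads[acc]
    ord <- acc[order(-reads)]
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!calls$accepted[i]) next
      others <- ord[-seq_len(a)]
      ovl <- others[calls$accepted[others] &
                      calls$chrom[others] == calls$chrom[i] &
                      calls$precursor_start[others] < calls$precursor_end[i] &
                      calls$precursor_end[others] > calls$precursor_start[i] &
                      calls$tag_seq[others] != calls$tag_seq[i]]
      if (length(ovl)) {
        calls$accepted[ovl] <- FALSE
        calls$reason[ovl] <- "star_arm_of_guide"
      }
    }
    keep_tags <- calls$tag_seq[calls$accepted]
    details <- details[vapply(details, function(d)
      d$locus$seq %in% keep_tags, logical(1))]
  }
  structure(list(calls = calls, details = details, libs = libs),
            class = "novel_mirna_result")
}

#' @export
print.novel_mirna_result <- function(x, ...) {
  cat(sprintf("<novel_mirna_result> %d evaluated loci, %d accepted novel miRNAs\n",
              nrow(x$calls), sum(x$calls$accepted)))
  invisible(x)
}
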