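## per-pair pseudo-energy magnitudes of the duplex engine:
## G:C 3, A:U 2, G:U 1 kcal/mol
PAIR_ENERGY <- c(A = 2, C = 3, G = 3, T = 2)

#' MFE of a miRNA bound to its perfect complement
#'
#' Under the package's per-pair duplex energy model (G:C -3, A:U -2 kcal/mol).
#'
#' @param mirna miRNA sequence (5' to 3').
#' @return negative energy in kcal/mol.
#' @export
perfect_duplex_mfe <- function(mirna) {
  mirna <- norm_seq(mirna)
  -sum(PAIR_ENERGY[strsplit(mirna, "")[[1]]])
}

## map alignment columns to miRNA positions; target-bulge columns ('B') are
## assigned the miRNA position they interrupt
column_positions <- function(states, gap_type, gap_pos) {
  n <- nchar(states)
  cols <- seq_len(n)
  if (gap_type == 1L) {
    pos <- ifelse(cols < gap_pos, cols, cols - 1L)
    pos[gap_pos] <- min(gap_pos, n - 1L)
  } else {
    pos <- cols
  }
  pos
}

#' Score a miRNA/target duplex alignment
#'
#' Weighted mismatch scoring: perfect match 0, G:U wobble 0.5, mismatch or
#' bulge 1. Positions are indexed 1-based from the miRNA 5' end.
#'
#' @param states alignment state string over columns: `M` match, `G` G:U,
#'   `X` mismatch, `B` bulged target base, `b` bulged miRNA base.
#' @param gap_type 0 none, 1 target bulge, 2 miRNA bulge.
#' @param gap_pos alignment column of the bulge (when `gap_type > 0`).
#' @return list with `mismatch_total`, `adjacent_max` (longest run of
#'   weighted-positive columns), `region_1_12` and `region_2_12` weighted
#'   totals, `adjacent_2_12` (longest weighted-positive run inside positions
#'   2-12) and `pos_10_11` (states at miRNA positions 10 and 11).
#' @export
score_duplex <- function(states, gap_type = 0L, gap_pos = 0L) {
  st <- strsplit(states, "")[[1]]
  w <- c(M = 0, G = 0.5, X = 1, B = 1, b = 1)[st]
  pos <- column_positions(states, gap_type, gap_pos)
  runs <- rle(w > 0)
  adjacent_max <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  in_seed <- pos >= 2 & pos <= 12
  runs_seed <- rle(w > 0 & in_seed)
  adjacent_2_12 <- if (any(runs_seed$values))
    max(runs_seed$lengths[runs_seed$values]) else 0L
  list(mismatch_total = sum(w),
       adjacent_max = adjacent_max,
       region_1_12 = sum(w[pos >= 1 & pos <= 12]),
       region_2_12 = sum(w[in_seed]),
       adjacent_2_12 = adjacent_2_12,
       pos_10_11 = st[pos %in% c(10, 11)])
}

#' Apply the six target-prediction rules to a scored duplex
#'
#' The rule set for plant miRNA target sites:
#' R1 total weighted mismatches <= 4 (G:U counts 0.5, bulges 1);
#' R2 no more than two adjacent mismatches;
#' R3 no adjacent mismatches within miRNA positions 2-12;
#' R4 miRNA positions 10-11 both paired (no mismatch or bulge);
#' R5 weighted mismatches within positions 1-12 <= 2.5;
#' R6 duplex MFE at least 75 percent of the perfect-complement MFE.
#'
#' @param states,gap_type,gap_pos as in [score_duplex()].
#' @param duplex_mfe duplex energy (kcal/mol, <= 0).
#' @param perfect_mfe perfect-complement energy (must be < 0).
#' @param max_total,max_seed,min_mfe_ratio rule thresholds (defaults 4, 2.5,
#'   0.75).
#' @return list with the six `R*` flags, `accepted` (their conjunction),
#'   `mismatch_total` and `mfe_ratio`.
#' @export
apply_rules <- function(states, duplex_mfe, perfect_mfe, gap_type = 0L,
                        gap_pos = 0L, max_total = 4, max_seed = 2.5,
                        min_mfe_ratio = 0.75) {
  assert_that(perfect_mfe < 0, "apply_rules(): perfect_mfe must be < 0")
  sc <- score_duplex(states, gap_type, gap_pos)
  ratio <- duplex_mfe / perfect_mfe
  flags <- c(R1 = sc$mismatch_total <= max_total,
             R2 = sc$adjacent_max <= 2,
             R3 = sc$adjacent_2_12 <= 1,
             R4 = length(sc$pos_10_11) == 2L && all(sc$pos_10_11 %in% c("M", "G")),
             R5 = sc$region_1_12 <= max_seed,
             R6 = ratio >= min_mfe_ratio)
  c(as.list(flags), list(accepted = all(flags),
                         mismatch_total = sc$mismatch_total,
                         mfe_ratio = ratio))
}

#' Scan transcripts for miRNA complementary target sites
#'
#' Slides each miRNA along each transcript with a banded complementarity
#' alignment (at most one 1-nt bulge on either strand), applies the six
#' rules of [apply_rules()], collapses overlapping candidate alignments at
#' one locus to the best-scoring duplex, and reports hits sorted by
#' ascending weighted mismatch total then descending MFE ratio. The
#' predicted cleavage position is the transcript base paired to miRNA
#' position 10 (slicing between positions 10 and 11).
#'
#' @param mirnas named character vector of mature miRNA sequences (>= 15 nt).
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path.
#' @param max_total,max_seed,min_mfe_ratio rule thresholds.
#' @return `data.frame` of class `target_hits`: `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end` (0-based half-open), `predicted_cleavage`,
#'   `mismatch_total`, `duplex_mfe`, `perfect_mfe`, `mfe_ratio`, `states`,
#'   and the `R1`..`R6` flags (all `TRUE` on reported rows).
#' @export
scan_targets <- function(mirnas, transcripts, max_total = 4, max_seed = 2.5,
                         min_mfe_ratio = 0.75) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- read_fasta_seqs(transcripts)
  assert_that(length(transcripts) > 0L, "scan_targets(): transcripts empty")
  mirnas <- norm_seq(mirnas)
  assert_that(all(nchar(mirnas) >= 15L),
              "scan_targets(): miRNAs must be at least 15 nt")
  transcripts <- norm_seq(transcripts)
  if (is.null(names(mirnas)))
    names(mirnas) <- paste0("mir", seq_along(mirnas))
  rows <- list()
  for (mi in names(mirnas)) {
    pm <- perfect_duplex_mfe(mirnas[[mi]])
    for (tx in names(transcripts)) {
      cand <- .duplex_scan_cpp(mirnas[[mi]], transcripts[[tx]], max_total)
      if (nrow(cand) == 0L) next
      res <- lapply(seq_len(nrow(cand)), function(i) {
        apply_rules(cand$states[i], cand$duplex_mfe[i], pm,
                    cand$gap_type[i], cand$gap_pos[i], max_total, max_seed,
                    min_mfe_ratio)
      })
      ok <- vapply(res, `[[`, logical(1), "accepted")
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]
      res <- res[ok]
      df <- data.frame(mirna_id = mi, transcript_id = tx,
                       site_start = cand$site_start,
                       site_end = cand$site_end,
                       predicted_cleavage = cand$cleavage,
                       mismatch_total = cand$mismatch_total,
                       duplex_mfe = cand$duplex_mfe, perfect_mfe = pm,
                       mfe_ratio = vapply(res, `[[`, numeric(1), "mfe_ratio"),
                       states = cand$states, stringsAsFactors = FALSE)
      for (r in paste0("R", 1:6))
        df[[r]] <- vapply(res, `[[`, logical(1), r)
      # collapse overlapping alignments at one locus to the best duplex
      df <- df[order(df$mismatch_total, -df$mfe_ratio), , drop = FALSE]
      keep <- rep(TRUE, nrow(df))
      for (i in seq_len(nrow(df))) {
        if (!keep[i]) next
        if (i < nrow(df)) {
          later <- (i + 1L):nrow(df)
          ovl <- df$site_start[later] < df$site_end[i] &
            df$site_end[later] > df$site_start[i]
          keep[later][ovl] <- FALSE
        }
      }
      rows[[length(rows) + 1L]] <- df[keep, , drop = FALSE]
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               site_start = integer(0), site_end = integer(0),
               predicted_cleavage = integer(0), mismatch_total = numeric(0),
               duplex_mfe = numeric(0), perfect_mfe = numeric(0),
               mfe_ratio = numeric(0), states = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$mismatch_total, -out$mfe_ratio), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_hits", "data.frame")
  out
}

#' @export
print.target_hits <- function(x, ...) {
  cat(sprintf("<target_hits> %d sites (%d miRNAs x %d transcripts)\n",
              nrow(x), length(unique(x$mirna_id)),
              length(unique(x$transcript_id))))
  NextMethod()
}
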