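#' Build per-transcript degradome 5'-end profiles
#'
#' Each degradome tag contributes its read count to the position of its
#' 5'-most aligned base on every transcript it matches exactly (sense
#' strand only). Tag counts are taken from count-encoded FASTA headers
#' (`..._x{count}`) and default to 1.
#'
#' @param tags named character vector of degradome tag sequences or a FASTA
#'   path; tags shorter than `min_len` are ignored.
#' @param transcripts named character vector or FASTA path.
#' @param min_len minimum tag length (default 18).
#' @return named list of `degradome_profile` objects, each with
#'   `transcript_id`, `depth` (count per 0-based position) and `total_tags`.
#' @export
build_profiles <- function(tags, transcripts, min_len = 18L) {
  if (is.character(tags) && length(tags) == 1L && file.exists(tags))
    tags <- read_fasta_seqs(tags)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- read_fasta_seqs(transcripts)
  tags <- norm_seq(tags)
  transcripts <- norm_seq(transcripts)
  counts <- rep(1L, length(tags))
  if (!is.null(names(tags))) {
    m <- regmatches(names(tags), regexpr("_x([0-9]+)$", names(tags)))
    has <- grepl("_x[0-9]+$", names(tags))
    counts[has] <- as.integer(sub("^_x", "", m))
  }
  ok <- nchar(tags) >= min_len
  tags <- tags[ok]; counts <- counts[ok]
  profiles <- lapply(names(transcripts), function(tx) {
    depth <- integer(nchar(transcripts[[tx]]))
    structure(list(transcript_id = tx, depth = depth, total_tags = 0L),
              class = "degradome_profile")
  })
  names(profiles) <- names(transcripts)
  if (length(tags)) {
    for (tx in names(transcripts)) {
      subject <- transcripts[[tx]]
      for (w in unique(nchar(tags))) {
        idx <- which(nchar(tags) == w)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags[idx]))
        m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject))
        st <- Biostrings::startIndex(m)
        for (k in seq_along(idx)) {
          s <- st[[k]]
          if (length(s)) {
            profiles[[tx]]$depth[s] <- profiles[[tx]]$depth[s] + counts[idx[k]]
            profiles[[tx]]$total_tags <-
              profiles[[tx]]$total_tags + counts[idx[k]] * length(s)
          }
        }
      }
    }
  }
  profiles
}

#' @export
print.degradome_profile <- function(x, ...) {
  cat(sprintf("<degradome_profile> %s: %d nt, %d tag 5' ends, max depth %d\n",
              x$transcript_id, length(x$depth), x$total_tags,
              if (length(x$depth)) max(x$depth) else 0L))
  invisible(x)
}

#' Degradome peak category at a transcript position
#'
#' CleaveLand-convention categories of the tag 5'-end depth at `pos`:
#' 0 unique maximum above the median of nonzero depths; 1 non-unique
#' maximum; 2 above the nonzero median but below the maximum; 3 at or below
#' the median; 4 a depth of exactly 1 (overrides 3). `NA` when the depth at
#' `pos` is zero.
#'
#' @param profile a `degradome_profile` (or bare depth vector).
#' @param pos 0-based transcript position.
#' @return integer category 0-4, or `NA`.
#' @export
categorize <- function(profile, pos) {
  depth <- if (inherits(profile, "degradome_profile")) profile$depth else profile
  assert_that(pos >= 0L && pos < length(depth),
              "categorize(): position out of range")
  d <- depth[pos + 1L]
  if (d == 0L) return(NA_integer_)
  nz <- depth[depth > 0L]
  med <- median(nz)
  mx <- max(depth)
  unique_max <- sum(depth == mx) == 1L
  if (d == mx && unique_max && mx > med) return(0L)
  if (d == mx && !unique_max) return(1L)
  if (d == 1L) return(4L)
  if (d > med) return(2L)
  3L
}

## Altschul-Erickson dinucleotide-preserving shuffle of one sequence.
## Draws from the RNG stream in effect; deterministic under set.seed().
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n <= 3L) return(seq)
  verts <- unique(ch)
  from <- ch[-n]; to <- ch[-1L]
  last <- ch[n]
  for (attempt in 1:100) {
    # pick a random final exit edge for every vertex except the end vertex;
    # they must form a tree pointing toward the end vertex
    final_to <- vapply(verts, function(v) {
      if (v == last) return(NA_character_)
      outs <- to[from == v]
      outs[sample.int(length(outs), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      cur <- v; steps <- 0L
      while (!identical(cur, last)) {
        cur <- final_to[[cur]]
        steps <- steps + 1L
        if (is.na(cur) || steps > length(verts)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    # order remaining out-edges randomly, final edge last; walk from start
    edge_lists <- lapply(verts, function(v) {
      outs <- to[from == v]
      if (!is.na(final_to[[v]])) {
        i <- match(final_to[[v]], outs)
        outs <- c(sample(outs[-i]), outs[i])
      } else {
        outs <- sample(outs)
      }
      outs
    })
    names(edge_lists) <- verts
    ptr <- setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- ch[1L]
    cur <- ch[1L]
    for (i in 2:n) {
      nxt <- edge_lists[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    return(paste(out, collapse = ""))
  }
  seq
}

#' Call miRNA-guided cleavage sites from degradome profiles
#'
#' For every rule-passing target site of [scan_targets()], looks up the
#' degradome depth at the predicted cleavage position (opposite miRNA
#' position 10), assigns its peak category, and computes a permutation
#' p-value: the fraction of dinucleotide-preserving miRNA shuffles that
#' produce an accepted duplex anywhere in the transcriptome whose cleavage
#' position has a category at least as good (numerically at most) as the
#' observed one, with the add-one correction
#' `(1 + successes) / (1 + n_perm)`. Calls with `pvalue < alpha` are
#' returned sorted by p-value.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector or FASTA path.
#' @param profiles from [build_profiles()].
#' @param n_perm number of shuffles (default 1000; below 100 warns).
#' @param seed RNG seed (required, for reproducible shuffles).
#' @param alpha reporting threshold (default 0.05).
#' @param hits optional precomputed `target_hits`; scanned afresh otherwise.
#' @return `data.frame` of class `cleavage_calls`: `mirna_id`,
#'   `transcript_id`, `cleavage_pos`, `peak_count`, `category`, `pvalue`,
#'   plus the duplex columns of the originating hit.
#' @export
call_sites <- function(mirnas, transcripts, profiles, n_perm = 1000L,
                       seed, alpha = 0.05, hits = NULL) {
  assert_that(!missing(seed), "call_sites(): seed is required")
  if (n_perm < 100L) warning("call_sites(): n_perm < 100 gives coarse p-values")
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- read_fasta_seqs(transcripts)
  mirnas <- norm_seq(mirnas)
  if (is.null(hits)) hits <- scan_targets(mirnas, transcripts)
  set.seed(seed)
  out <- list()
  for (mi in unique(hits$mirna_id)) {
    sub <- hits[hits$mirna_id == mi, , drop = FALSE]
    obs <- lapply(seq_len(nrow(sub)), function(i) {
      pr <- profiles[[sub$transcript_id[i]]]
      pos <- sub$predicted_cleavage[i]
      cat <- categorize(pr, pos)
      list(pos = pos, cat = cat, count = pr$depth[pos + 1L])
    })
    cats <- vapply(obs, function(o) ifelse(is.na(o$cat), NA_integer_, o$cat),
                   integer(1))
    if (all(is.na(cats))) next
    # best (minimum) category reached by each shuffled miRNA anywhere;
    # lean inner loop: raw candidate scan + rule check, no sorting/collapse
    perm_best <- vapply(seq_len(n_perm), function(p) {
      sh <- dinucleotide_shuffle(mirnas[[mi]])
      pm <- perfect_duplex_mfe(sh)
      best <- NA_integer_
      for (tx in names(transcripts)) {
        cand <- .duplex_scan_cpp(sh, transcripts[[tx]], 4)
        for (j in seq_len(nrow(cand))) {
          rl <- apply_rules(cand$states[j], cand$duplex_mfe[j], pm,
                            cand$gap_type[j], cand$gap_pos[j])
          if (!rl$accepted) next
          cc <- categorize(profiles[[tx]], cand$cleavage[j])
          if (!is.na(cc) && (is.na(best) || cc < best)) best <- cc
        }
      }
      best
    }, integer(1))
    for (i in seq_len(nrow(sub))) {
      if (is.na(cats[i])) next
      succ <- sum(!is.na(perm_best) & perm_best <= cats[i])
      pv <- (1 + succ) / (1 + n_perm)
      row <- sub[i, , drop = FALSE]
      row$cleavage_pos <- obs[[i]]$pos
      row$peak_count <- obs[[i]]$count
      row$category <- cats[i]
      row$pvalue <- pv
      out[[length(out) + 1L]] <- row
    }
  }
  res <- if (length(out)) do.call(rbind, out) else cbind(
    hits[0, , drop = FALSE],
    data.frame(cleavage_pos = integer(0), peak_count = integer(0),
               category = integer(0), pvalue = numeric(0)))
  res <- res[!is.na(res$pvalue) & res$pvalue < alpha, , drop = FALSE]
  res <- res[order(res$pvalue, res$mismatch_total), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cleavage_calls", "data.frame")
  res
}

#' @export
print.cleavage_calls <- function(x, ...) {
  cat(sprintf("<cleavage_calls> %d sites with p < 0.05 (%d at category 0)\n",
              nrow(x), sum(x$category == 0)))
  NextMethod()
}

#' t-plot data for one cleavage call
#'
#' The per-position degradome depth series with the called cleavage
#' coordinate marked; rendering (see [plot.tplot()]) is a thin layer over
#' this data.
#'
#' @param profile a `degradome_profile`.
#' @param call one-row `cleavage_calls` entry for the same transcript
#'   (optional; `NULL` gives an unmarked series).
#' @return object of class `tplot`: list with `data` (`data.frame`:
#'   `position`, `count`) and `cleavage_pos`.
#' @export
tplot <- function(profile, call = NULL) {
  if (!is.null(call))
    assert_that(call$transcript_id == profile$transcript_id,
                "tplot(): call does not reference this transcript")
  n <- length(profile$depth)
  structure(list(
    transcript_id = profile$transcript_id,
    data = data.frame(position = seq_len(n) - 1L, count = profile$depth),
    cleavage_pos = if (is.null(call)) NA_integer_ else call$cleavage_pos),
    class = "tplot")
}

#' @export
plot.tplot <- function(x, ...) {
  graphics::plot(x$data$position, x$data$count, type = "h",
                 xlab = "transcript position (nt)",
                 ylab = "degradome tag 5' ends",
                 main = x$transcript_id, ...)
  if (!is.na(x$cleavage_pos))
    graphics::abline(v = x$cleavage_pos, col = "red")
  invisible(x)
}

#' @export
print.tplot <- function(x, ...) {
  cat(sprintf("<tplot> %s: %d positions, cleavage at %s\n", x$transcript_id,
              nrow(x$data), ifelse(is.na(x$cleavage_pos), "none",
                                   x$cleavage_pos)))
  invisible(x)
}
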