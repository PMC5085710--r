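TAG_CATEGORIES <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                    "exon_sense", "exon_antisense", "intron_sense",
                    "intron_antisense", "unannotated")

#' Read a FASTQ file
#'
#' Minimal Sanger-quality FASTQ reader. Malformed records are reported with
#' their record index.
#'
#' @param path FASTQ file path.
#' @return `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  assert_that(length(lines) %% 4L == 0L,
              sprintf("read_fastq(): truncated FASTQ record %d", length(lines) %/% 4L + 1L))
  n <- length(lines) %/% 4L
  id <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(id, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  assert_that(length(bad) == 0L,
              sprintf("read_fastq(): malformed FASTQ record %d", bad[1L]))
  data.frame(id = sub("^@", "", id), seq = norm_seq(seq), qual = qual,
             stringsAsFactors = FALSE)
}

## number of mismatches between a read prefix and a full adapter (equal length)
.prefix_mismatches <- function(read_prefix, adapter) {
  a <- strsplit(read_prefix, "")[[1]]
  b <- strsplit(adapter, "")[[1]]
  sum(a != b)
}

#' Trim adapters and filter raw small-RNA reads
#'
#' Cleans a raw small-RNA library: strips the 5' adapter when the read
#' starts with it (at most 1 mismatch over its length), locates the 3'
#' adapter as the leftmost position where the read suffix matches an adapter
#' prefix of at least `min_overlap` nt with at most one mismatch (the
#' longest-prefix rule), and then discards inserts that are low quality
#' (mean Phred below `min_qual`), contain `N`, are at least 80 percent
#' adenine (the polyA rule), or fall outside `[min_len, max_len]`. Reads
#' without a recognizable 3' adapter are discarded as contaminants.
#'
#' @param reads a `data.frame` from [read_fastq()], or a character vector of
#'   read sequences (then no quality filtering is done).
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 5' adapter sequence ("" to skip 5' handling).
#' @param min_len,max_len insert length bounds (defaults 18 and 30 nt).
#' @param min_qual minimum mean Phred quality (default 20; this threshold is
#'   a configuration knob, not a published value).
#' @param min_overlap minimum 3' adapter overlap (default 5 nt).
#' @param polyA_frac adenine fraction at or above which an insert is
#'   discarded as polyA (default 0.8).
#' @return list with `inserts` (character vector of clean insert sequences)
#'   and `log` (named integer vector of per-reason discard counts, plus
#'   `input` and `kept`).
#' @export
trim_and_filter <- function(reads, adapter3, adapter5 = "",
                            min_len = 18L, max_len = 30L, min_qual = 20,
                            min_overlap = 5L, polyA_frac = 0.8) {
  assert_that(nzchar(adapter3), "trim_and_filter(): adapter3 must be non-empty")
  assert_that(min_len <= max_len, "trim_and_filter(): min_len > max_len")
  if (is.data.frame(reads)) {
    seqs <- norm_seq(reads$seq)
    quals <- reads$qual
  } else {
    seqs <- norm_seq(reads)
    quals <- NULL
  }
  adapter3 <- norm_seq(adapter3)
  log <- c(input = length(seqs), low_quality = 0L, no_adapter = 0L,
           adapter5_contaminant = 0L, has_N = 0L, polyA = 0L,
           too_short = 0L, too_long = 0L, kept = 0L)
  if (length(seqs) == 0L) {
    warning("trim_and_filter(): empty input stream")
    return(list(inserts = character(0), log = log))
  }
  keep <- rep(TRUE, length(seqs))
  if (!is.null(quals)) {
    mq <- .mean_phred_cpp(quals)
    bad <- keep & mq < min_qual
    log["low_quality"] <- sum(bad)
    keep <- keep & !bad
  }
  # 5' adapter: strip when the read starts with it (<= 1 mismatch)
  if (nzchar(adapter5)) {
    adapter5 <- norm_seq(adapter5)
    a5len <- nchar(adapter5)
    long_enough <- keep & nchar(seqs) > a5len
    pref <- substr(seqs, 1L, a5len)
    mm <- vapply(pref[long_enough], .prefix_mismatches, numeric(1),
                 adapter = adapter5, USE.NAMES = FALSE)
    strip <- rep(FALSE, length(seqs))
    strip[long_enough][mm <= 1] <- TRUE
    seqs[strip] <- substr(seqs[strip], a5len + 1L, nchar(seqs[strip]))
  }
  pos <- .locate_adapter3_cpp(seqs, adapter3, as.integer(min_overlap))
  bad <- keep & pos < 0L
  log["no_adapter"] <- sum(bad)
  keep <- keep & !bad
  inserts <- substr(seqs, 1L, pmax(pos, 0L))
  if (nzchar(adapter5)) {
    bad <- keep & grepl(adapter5, inserts, fixed = TRUE)
    log["adapter5_contaminant"] <- sum(bad)
    keep <- keep & !bad
  }
  bad <- keep & grepl("N", inserts, fixed = TRUE)
  log["has_N"] <- sum(bad)
  keep <- keep & !bad
  len <- nchar(inserts)
  a_frac <- ifelse(len > 0, nchar(gsub("[^A]", "", inserts)) / pmax(len, 1L), 1)
  bad <- keep & a_frac >= polyA_frac
  log["polyA"] <- sum(bad)
  keep <- keep & !bad
  bad <- keep & len < min_len
  log["too_short"] <- sum(bad)
  keep <- keep & !bad
  bad <- keep & len > max_len
  log["too_long"] <- sum(bad)
  keep <- keep & !bad
  log["kept"] <- sum(keep)
  list(inserts = inserts[keep], log = log)
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' @param libraries named list of character vectors, one per library, each a
#'   vector of clean insert sequences.
#' @return a `tag_table`: `data.frame` with `seq`, one count column per
#'   library, and `category` (initialized to `"unannotated"`).
#' @export
collapse_tags <- function(libraries) {
  assert_that(is.list(libraries) && length(libraries) >= 1L,
              "collapse_tags(): need a named list of libraries")
  if (is.null(names(libraries)) || any(!nzchar(names(libraries))))
    names(libraries) <- paste0("lib", seq_along(libraries))
  all_seqs <- sort(unique(unlist(libraries, use.names = FALSE)))
  out <- data.frame(seq = all_seqs, stringsAsFactors = FALSE)
  for (nm in names(libraries)) {
    tab <- table(factor(libraries[[nm]], levels = all_seqs))
    out[[nm]] <- as.integer(tab)
  }
  out$category <- "unannotated"
  attr(out, "libs") <- names(libraries)
  class(out) <- c("tag_table", "data.frame")
  out
}

count_cols <- function(tags) attr(tags, "libs")

## TRUE for each tag that is an exact substring of any reference sequence,
## on either strand.
tags_in_reference <- function(tag_seqs, ref_seqs) {
  if (length(ref_seqs) == 0L || length(tag_seqs) == 0L)
    return(rep(FALSE, length(tag_seqs)))
  subjects <- Biostrings::DNAStringSet(c(ref_seqs, revcomp(ref_seqs)))
  hit <- rep(FALSE, length(tag_seqs))
  for (w in unique(nchar(tag_seqs))) {
    idx <- which(nchar(tag_seqs) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tag_seqs[idx]))
    cnt <- rowSums(Biostrings::vcountPDict(pd, subjects))
    hit[idx] <- cnt > 0
  }
  hit
}

#' Map tag sequences to exact genomic loci (both strands)
#'
#' @param tag_seqs character vector of tag sequences.
#' @param genome named character vector of chromosome sequences, or a FASTA
#'   path.
#' @param max_loci tags matching more than this many loci are dropped as
#'   repeats (default 20).
#' @return `data.frame` with `seq`, `chrom`, `start`, `end` (0-based,
#'   half-open), `strand`.
#' @export
map_tags_genome <- function(tag_seqs, genome, max_loci = 20L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta_seqs(genome)
  gen <- Biostrings::DNAStringSet(unname(genome))
  names(gen) <- names(genome)
  res <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") tag_seqs else revcomp(tag_seqs)
    for (w in unique(nchar(qs))) {
      idx <- which(nchar(qs) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(qs[idx]))
      for (chr in names(genome)) {
        m <- Biostrings::matchPDict(pd, gen[[chr]])
        st <- Biostrings::startIndex(m)
        for (k in seq_along(idx)) {
          s <- st[[k]]
          if (length(s))
            res[[length(res) + 1L]] <- data.frame(
              seq = tag_seqs[idx[k]], chrom = chr, start = s - 1L,
              end = s - 1L + w, strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(seq = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  n_loci <- table(out$seq)
  repeats <- names(n_loci)[n_loci > max_loci]
  out[!(out$seq %in% repeats), , drop = FALSE]
}

#' Partition unique tags into annotation categories
#'
#' Assigns each tag the first matching category in the fixed precedence
#' order `miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon_sense >
#' exon_antisense > intron_sense > intron_antisense > unannotated`,
#' mirroring the sequential filtering of a small-RNA annotation pipeline.
#' ncRNA/repeat/miRNA categories match when the tag is an exact substring of
#' any reference sequence (either strand); exon/intron sense/antisense are
#' assigned from the strand-aware overlap of the tag's exact genomic matches
#' with gene models.
#'
#' @param tags a `tag_table` from [collapse_tags()].
#' @param references named list of reference sequence sets (character
#'   vectors or FASTA paths); allowed names: `miRNA`, `rRNA`, `tRNA`,
#'   `snRNA`, `snoRNA`, `repeat`.
#' @param gene_models GFF3 path or a `GRanges` with `type` values `gene` and
#'   `exon` (optional).
#' @param genome named character vector or FASTA path (optional; needed for
#'   exon/intron categories).
#' @return the `tag_table` with `category` filled in.
#' @export
classify_tags <- function(tags, references = list(), gene_models = NULL,
                          genome = NULL) {
  ref_cats <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat")
  bad <- setdiff(names(references), ref_cats)
  assert_that(length(bad) == 0L,
              paste0("classify_tags(): unknown reference category: ",
                     paste(bad, collapse = ", ")))
  references <- lapply(references, function(r) {
    if (is.character(r) && length(r) == 1L && file.exists(r))
      read_fasta_seqs(r) else norm_seq(r)
  })
  cat <- rep("unannotated", nrow(tags))
  for (rc in ref_cats) {
    if (is.null(references[[rc]])) next
    open <- cat == "unannotated"
    if (!any(open)) break
    hit <- tags_in_reference(tags$seq[open], references[[rc]])
    cat[open][hit] <- rc
  }
  if (!is.null(gene_models) && !is.null(genome)) {
    gm <- if (is.character(gene_models)) rtracklayer::import(gene_models) else gene_models
    open <- which(cat == "unannotated")
    if (length(open)) {
      loci <- map_tags_genome(tags$seq[open], genome)
      if (nrow(loci)) {
        gr <- GenomicRanges::GRanges(
          loci$chrom,
          IRanges::IRanges(loci$start + 1L, loci$end), strand = loci$strand)
        feats <- list(
          exon = gm[tolower(as.character(gm$type)) == "exon"],
          gene = gm[tolower(as.character(gm$type)) == "gene"])
        lab <- rep(NA_character_, length(gr))
        for (ft in c("exon", "gene")) {
          f <- feats[[ft]]
          if (length(f) == 0L) next
          ov <- GenomicRanges::findOverlaps(gr, f, ignore.strand = TRUE)
          if (length(ov) == 0L) next
          same <- as.character(GenomicRanges::strand(gr))[S4Vectors::queryHits(ov)] ==
            as.character(GenomicRanges::strand(f))[S4Vectors::subjectHits(ov)]
          base <- if (ft == "exon") "exon" else "intron"
          for (i in seq_along(ov)) {
            q <- S4Vectors::queryHits(ov)[i]
            new_lab <- paste0(base, if (same[i]) "_sense" else "_antisense")
            cur <- lab[q]
            if (is.na(cur) ||
                match(new_lab, TAG_CATEGORIES) < match(cur, TAG_CATEGORIES))
              lab[q] <- new_lab
          }
        }
        # per tag: best (highest-precedence) label over all its loci
        per_tag <- tapply(lab, loci$seq, function(v) {
          v <- v[!is.na(v)]
          if (!length(v)) NA_character_ else
            TAG_CATEGORIES[min(match(v, TAG_CATEGORIES))]
        })
        hit <- match(tags$seq[open], names(per_tag))
        assigned <- !is.na(hit) & !is.na(per_tag[hit])
        cat[open][assigned] <- unname(per_tag[hit][assigned])
      }
    }
  }
  tags$category <- cat
  tags
}

#' Table-style per-category library summary
#'
#' One row per annotation category (plus a `Total` row) with unique-tag and
#' total-read counts and percentages for each library.
#'
#' @param tags a classified `tag_table`.
#' @return `data.frame` of class `library_summary`.
#' @export
tag_summary <- function(tags) {
  libs <- count_cols(tags)
  rows <- c("Total", TAG_CATEGORIES)
  out <- data.frame(category = rows, stringsAsFactors = FALSE)
  for (nm in libs) {
    cnt <- tags[[nm]]
    present <- cnt > 0
    uq_tot <- sum(present)
    to_tot <- sum(cnt)
    uq <- vapply(TAG_CATEGORIES, function(cc)
      sum(present & tags$category == cc), integer(1))
    to <- vapply(TAG_CATEGORIES, function(cc)
      sum(cnt[tags$category == cc]), integer(1))
    out[[paste0("unique_", nm)]] <- c(uq_tot, uq)
    out[[paste0("unique_pct_", nm)]] <-
      round(c(100, if (uq_tot > 0) uq / uq_tot * 100 else uq * 0), 2)
    out[[paste0("total_", nm)]] <- c(to_tot, to)
    out[[paste0("total_pct_", nm)]] <-
      round(c(100, if (to_tot > 0) to / to_tot * 100 else to * 0), 2)
  }
  class(out) <- c("library_summary", "data.frame")
  out
}

#' Library overlap (common vs library-specific tags)
#'
#' Computes the common / specific-to-A / specific-to-B partition both over
#' distinct tag sequences (`unique` view, fractions of the union) and over
#' summed read counts (`total` view, fractions of the grand total). Each
#' view's three fractions sum to 1. `per_library_common` gives the fraction
#' of each library's own reads carried by tags shared with the other
#' library.
#'
#' @param tags a `tag_table` with exactly two libraries.
#' @return list with `unique`, `total` (each `c(common, specificA,
#'   specificB)`) and `per_library_common`.
#' @export
library_overlap <- function(tags) {
  libs <- count_cols(tags)
  assert_that(length(libs) == 2L, "library_overlap(): exactly two libraries required")
  a <- tags[[libs[1]]]
  b <- tags[[libs[2]]]
  assert_that(sum(a) > 0 && sum(b) > 0, "library_overlap(): both libraries must be non-empty")
  shared <- a > 0 & b > 0
  onlyA <- a > 0 & b == 0
  onlyB <- b > 0 & a == 0
  n_union <- sum(shared | onlyA | onlyB)
  grand <- sum(a) + sum(b)
  list(
    unique = c(common = sum(shared) / n_union,
               specificA = sum(onlyA) / n_union,
               specificB = sum(onlyB) / n_union),
    total = c(common = (sum(a[shared]) + sum(b[shared])) / grand,
              specificA = sum(a[onlyA]) / grand,
              specificB = sum(b[onlyB]) / grand),
    per_library_common = setNames(
      c(sum(a[shared]) / sum(a), sum(b[shared]) / sum(b)), libs))
}

#' Write a collapsed-tag FASTA
#'
#' Headers follow the `tag{n}_x{count_lib1}_y{count_lib2}` convention.
#'
#' @param tags a `tag_table` with two libraries.
#' @param path output FASTA path.
#' @export
write_tag_fasta <- function(tags, path) {
  libs <- count_cols(tags)
  hdr <- sprintf("tag%d_x%d_y%d", seq_len(nrow(tags)),
                 tags[[libs[1]]], if (length(libs) > 1) tags[[libs[2]]] else 0L)
  write_fasta_seqs(setNames(tags$seq, hdr), path)
}
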