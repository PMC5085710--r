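## Parse miRBase-style mature IDs into family and arm.
## "gma-miR160a-5p" -> family "miR160", arm "5p"; arm "unknown" when absent.
parse_mirna_id <- function(ids) {
  arm <- ifelse(grepl("[-_](5p|3p)$", ids),
                sub(".*[-_](5p|3p)$", "\\1", ids), "unknown")
  core <- sub("[-_](5p|3p)$", "", ids)
  core <- sub("^[a-z]{2,4}-", "", core)                 # species prefix
  fam <- sub("^((miR|MIR|novel_mir_?)[0-9]+).*$", "\\1", core)
  data.frame(mirna_id = ids, family = fam, arm = arm, stringsAsFactors = FALSE)
}

#' Identify conserved miRNAs by perfect match to a mature reference
#'
#' A tag is a hit iff its sequence equals a reference mature sequence
#' exactly (after U-to-T normalization). Hits carry every matching reference
#' ID; tags matching references from more than one family are flagged
#' ambiguous. Non-matching tags are returned as the residual set for novel
#' prediction.
#'
#' @param tags a `tag_table`.
#' @param mature_ref named character vector of mature miRNA sequences, or a
#'   miRBase-style FASTA path. IDs are parsed as family plus optional
#'   `-5p`/`-3p` arm suffix.
#' @return list of class `known_mirna_result` with `hits` (`data.frame`:
#'   `tag_seq`, `mirna_id`, `family`, `arm`, one count column per library,
#'   `ambiguous`) and `residual` (the non-matching `tag_table` rows).
#' @export
match_known <- function(tags, mature_ref) {
  if (is.character(mature_ref) && length(mature_ref) == 1L &&
      file.exists(mature_ref))
    mature_ref <- read_fasta_seqs(mature_ref)
  ref_seq <- norm_seq(mature_ref)
  assert_that(!is.null(names(ref_seq)) && all(nzchar(names(ref_seq))),
              "match_known(): reference sequences must be named")
  dup <- duplicated(names(ref_seq))
  if (any(dup)) {
    clash <- vapply(unique(names(ref_seq)[dup]), function(id)
      length(unique(ref_seq[names(ref_seq) == id])) > 1L, logical(1))
    assert_that(!any(clash),
                "match_known(): duplicate reference IDs with different sequences")
    ref_seq <- ref_seq[!dup]
  }
  libs <- count_cols(tags)
  meta <- parse_mirna_id(names(ref_seq))
  is_hit <- tags$seq %in% ref_seq
  hits <- do.call(rbind, lapply(which(is_hit), function(i) {
    m <- which(ref_seq == tags$seq[i])
    h <- data.frame(tag_seq = tags$seq[i], mirna_id = names(ref_seq)[m],
                    family = meta$family[m], arm = meta$arm[m],
                    stringsAsFactors = FALSE)
    for (nm in libs) h[[nm]] <- tags[[nm]][i]
    h$ambiguous <- length(unique(meta$family[m])) > 1L
    h
  }))
  if (is.null(hits))
    hits <- data.frame(tag_seq = character(0), mirna_id = character(0),
                       family = character(0), arm = character(0),
                       ambiguous = logical(0), stringsAsFactors = FALSE)
  residual <- tags[!is_hit, , drop = FALSE]
  attr(residual, "libs") <- libs
  class(residual) <- class(tags)
  structure(list(hits = hits, residual = residual, libs = libs),
            class = "known_mirna_result")
}

#' @export
print.known_mirna_result <- function(x, ...) {
  cat(sprintf("<known_mirna_result> %d hit tags (%d reference matches, %d families), %d residual tags\n",
              length(unique(x$hits$tag_seq)), nrow(x$hits),
              length(unique(x$hits$family)), nrow(x$residual)))
  invisible(x)
}

#' Per-family summary of known-miRNA hits
#'
#' @param known a `known_mirna_result` from [match_known()].
#' @return `data.frame` with one row per family: number of distinct mature
#'   sequences, 5p/3p/unknown-arm tallies, and per-library read totals.
#' @export
family_summary <- function(known) {
  h <- known$hits
  libs <- known$libs
  fams <- sort(unique(h$family))
  out <- do.call(rbind, lapply(fams, function(f) {
    sub <- h[h$family == f, , drop = FALSE]
    sub1 <- sub[!duplicated(sub$tag_seq), , drop = FALSE]
    row <- data.frame(family = f, n_sequences = nrow(sub1),
                      n_5p = sum(sub$arm == "5p"),
                      n_3p = sum(sub$arm == "3p"),
                      n_unknown_arm = sum(sub$arm == "unknown"),
                      ambiguous = any(sub$ambiguous),
                      stringsAsFactors = FALSE)
    for (nm in libs) row[[paste0("reads_", nm)]] <- sum(sub1[[nm]])
    row
  }))
  if (is.null(out))
    out <- data.frame(family = character(0), n_sequences = integer(0),
                      stringsAsFactors = FALSE)
  out
}
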