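#' Normalize a nucleotide sequence to the internal DNA alphabet
#'
#' Uppercases and converts U to T. All internal sequences in the package are
#' DNA-alphabet uppercase strings; FASTA/FASTQ readers pass through here.
#'
#' @param x character vector of sequences.
#' @return character vector, uppercase with U replaced by T.
#' @export
norm_seq <- function(x) {
  out <- chartr("u", "T", chartr("U", "T", toupper(as.character(x))))
  names(out) <- names(x)
  out
}

#' Reverse complement (DNA alphabet)
#'
#' @param x character vector of ACGTN sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## Read a FASTA file into a named character vector (T/U-normalized).
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- norm_seq(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

## Write a named character vector as FASTA.
write_fasta_seqs <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

## gc fraction of a sequence string
gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(0)
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / n
}

## stopifnot with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
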