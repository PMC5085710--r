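# Small in-code fixtures shared by the unit tests.

# a tag_table built directly from per-library sequence vectors
toy_tags <- function(ms, mf) {
  collapse_tags(list(MS = ms, MF = mf))
}

# wrap plain sequences into FASTQ records with uniform high quality
as_fastq_df <- function(seqs, qual_char = "I") {
  data.frame(id = paste0("r", seq_along(seqs)), seq = seqs,
             qual = strrep(qual_char, nchar(seqs)), stringsAsFactors = FALSE)
}

# deterministic random DNA
rseq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
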