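#' Fold a candidate precursor sequence
#'
#' Computes a minimum-free-energy secondary structure in dot-bracket notation
#' together with the hairpin-quality statistics used to filter candidate
#' miRNA precursors: MFE (kcal/mol), AMFE (MFE normalized per 100 nt) and
#' MFEI (AMFE divided by the GC percentage).
#'
#' The folding engine is pluggable. The default `"nussinov"` engine is a
#' deterministic base-pair-maximization folder (compiled) over Watson-Crick
#' and G:U pairs with a minimum hairpin loop of 3 nt; the reported MFE is a
#' fixed pseudo-energy of -2 kcal/mol per pair, and the folder's pair counts
#' are validated against an exhaustive dynamic-programming oracle in the
#' test suite. The `"vienna"` engine calls
#' the ViennaRNA `RNAfold` binary (thermodynamic nearest-neighbor model) when
#' it is installed; all downstream structure logic is engine-agnostic because
#' it consumes only the dot-bracket string and the energy.
#'
#' @param seq a single nucleotide sequence (ACGT/U; U is normalized to T).
#' @param engine `"nussinov"` (default) or `"vienna"`.
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (nussinov engine only).
#' @return an object of class `precursor_fold`: a list with `seq`,
#'   `structure` (dot-bracket), `mfe` (kcal/mol, <= 0), `length`,
#'   `gc_percent`, `amfe` and `mfei`.
#' @examples
#' f <- fold(paste0(strrep("G", 10), "AAACAA", strrep("C", 10)))
#' f$mfei
#' @export
fold <- function(seq, engine = c("nussinov", "vienna"), min_loop = 3L) {
  engine <- match.arg(engine)
  seq <- norm_seq(seq)
  assert_that(length(seq) == 1L && nchar(seq) > 0L, "fold() needs one non-empty sequence")
  assert_that(!grepl("[^ACGT]", seq), "fold(): sequence contains non-ACGT characters")
  if (engine == "nussinov") {
    res <- .nussinov_fold_cpp(seq, as.integer(min_loop))
    structure_db <- res$structure
    # fixed per-pair pseudo-energy: -2 kcal/mol per base pair
    mfe <- -2 * as.numeric(res$score)
  } else {
    out <- system2("RNAfold", args = c("--noPS"),
                   input = chartr("T", "U", seq), stdout = TRUE)
    line <- out[2L]
    structure_db <- sub("\\s.*$", "", line)
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  }
  n <- nchar(seq)
  gcp <- gc_fraction(seq) * 100
  amfe <- abs(mfe) / n * 100
  # GC = 0 precursors get MFEI 0 (they fail the > 0.8 filter) rather than Inf
  mfei <- if (gcp > 0) amfe / gcp else 0
  structure(list(seq = seq, structure = structure_db, mfe = mfe, length = n,
                 gc_percent = gcp, amfe = amfe, mfei = mfei,
                 n_pairs = sum(strsplit(structure_db, "")[[1]] == "("),
                 engine = engine),
            class = "precursor_fold")
}

#' @export
print.precursor_fold <- function(x, ...) {
  cat(sprintf("<precursor_fold> %d nt, MFE %.2f kcal/mol, AMFE %.2f, GC %.1f%%, MFEI %.3f [%s]\n",
              x$length, x$mfe, x$amfe, x$gc_percent, x$mfei, x$engine))
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Base-pair partner table of a dot-bracket structure
#'
#' @param structure a dot-bracket string.
#' @return integer vector `p` with `p[i]` = 1-based partner of position `i`,
#'   or 0 when unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  p <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      assert_that(length(stack) > 0L, "pair_table(): unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  assert_that(length(stack) == 0L, "pair_table(): unbalanced brackets")
  p
}
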