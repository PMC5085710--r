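#' Assemble a pipeline configuration
#'
#' Collects the input paths and every stage parameter, with defaults at the
#' conventional values (18-30 nt length window, 0.001 zero substitution,
#' fold-change bands 2 and 1.2, alpha 0.05, MFEI threshold 0.8, 250 nt
#' excision flanks, 1000 permutations). The effective configuration is
#' serialized next to the outputs on every run.
#'
#' @param fastq_ms,fastq_mf the two library FASTQs (MS and MF).
#' @param genome genome FASTA.
#' @param gene_models GFF3 gene models.
#' @param mature_ref mature miRNA reference FASTA.
#' @param refs named list of ncRNA/repeat reference FASTA paths
#'   (`rRNA`, `tRNA`, `snRNA`, `snoRNA`, `repeat`).
#' @param transcripts transcript FASTA (target/degradome stages; optional).
#' @param degradome degradome tag FASTA (optional).
#' @param seed seed for the degradome permutation test.
#' @param ... parameter overrides (`adapter3`, `adapter5`, `min_len`,
#'   `max_len`, `min_qual`, `alpha`, `high_band`, `low_band`, `mfei_min`,
#'   `min_mature_reads`, `flank_up`, `flank_down`, `max_loci`, `n_perm`,
#'   `engine`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fastq_ms, fastq_mf, genome, gene_models,
                            mature_ref, refs, transcripts = NULL,
                            degradome = NULL, seed = 1L, ...) {
  cfg <- list(fastq_ms = fastq_ms, fastq_mf = fastq_mf, genome = genome,
              gene_models = gene_models, mature_ref = mature_ref,
              refs = refs, transcripts = transcripts, degradome = degradome,
              seed = as.integer(seed),
              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
              adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
              min_len = 18L, max_len = 30L, min_qual = 20,
              alpha = 0.05, high_band = 2, low_band = 1.2,
              mfei_min = 0.8, min_mature_reads = 5L,
              flank_up = 250L, flank_down = 250L, max_loci = 20L,
              n_perm = 1000L, engine = "nussinov")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  assert_that(length(bad) == 0L,
              paste0("pipeline_config(): unknown field(s): ",
                     paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

check_config_paths <- function(config) {
  keys <- c("fastq_ms", "fastq_mf", "genome", "gene_models", "mature_ref")
  for (k in keys)
    assert_that(!is.null(config[[k]]) && file.exists(config[[k]]),
                sprintf("run_pipeline(): missing or unreadable input for config key '%s'", k))
  for (k in names(config$refs))
    assert_that(file.exists(config$refs[[k]]),
                sprintf("run_pipeline(): missing reference file for config key 'refs$%s'", k))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tag_tsv <- function(path, libs) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  attr(df, "libs") <- libs
  class(df) <- c("tag_table", "data.frame")
  df
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes preprocess (trim, collapse, classify, summarize), known-miRNA
#' identification, novel-miRNA prediction, differential expression, target
#' prediction and degradome cleavage calling, writing plain TSV/FASTA/JSON
#' outputs per stage plus a manifest with the seed, package version and
#' per-stage record counts. With `resume = TRUE`, stages whose output files
#' already exist are reloaded instead of recomputed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param resume reload existing stage outputs when present.
#' @return list of class `pipeline_result` with every stage's objects and
#'   the manifest.
#' @export
run_pipeline <- function(config, outdir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  check_config_paths(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  libs <- c("MS", "MF")
  manifest <- list(package = "budmiR",
                   version = as.character(utils::packageVersion("budmiR")),
                   seed = config$seed)

  ## stage 1: preprocess -----------------------------------------------
  stage_files <- c(out("tags.tsv"), out("discard_log.json"))
  if (resume && all(file.exists(stage_files))) {
    tags <- read_tag_tsv(out("tags.tsv"), libs)
    logs <- jsonlite::read_json(out("discard_log.json"), simplifyVector = TRUE)
  } else {
    logs <- list()
    cleaned <- list()
    for (i in 1:2) {
      fq <- read_fastq(config[[c("fastq_ms", "fastq_mf")[i]]])
      tf <- trim_and_filter(fq, config$adapter3, config$adapter5,
                            config$min_len, config$max_len, config$min_qual)
      cleaned[[libs[i]]] <- tf$inserts
      logs[[libs[i]]] <- as.list(tf$log)
    }
    tags <- collapse_tags(cleaned)
    tags <- classify_tags(tags, references = c(
      list(miRNA = config$mature_ref), config$refs),
      gene_models = config$gene_models, genome = config$genome)
    write_tsv(tags, out("tags.tsv"))
    write_tag_fasta(tags, out("tags.fa"))
    jsonlite::write_json(logs, out("discard_log.json"), auto_unbox = TRUE)
    write_tsv(tag_summary(tags), out("summary.tsv"))
    jsonlite::write_json(lapply(library_overlap(tags), as.list),
                         out("overlap.json"), auto_unbox = TRUE, digits = NA)
  }
  N1 <- sum(tags$MS); N2 <- sum(tags$MF)
  manifest$preprocess <- list(clean_MS = N1, clean_MF = N2,
                              unique_tags = nrow(tags))

  ## stage 2: known miRNAs ---------------------------------------------
  known <- match_known(tags, config$mature_ref)
  write_tsv(known$hits, out("known_hits.tsv"))
  write_tsv(family_summary(known), out("family_summary.tsv"))
  manifest$known <- list(hits = nrow(known$hits),
                         families = length(unique(known$hits$family)),
                         residual = nrow(known$residual))

  ## stage 3: novel miRNAs ---------------------------------------------
  if (resume && file.exists(out("novel_calls.tsv"))) {
    novel_calls <- read.delim(out("novel_calls.tsv"), stringsAsFactors = FALSE)
    novel <- list(calls = novel_calls, details = list())
  } else {
    residual <- known$residual[known$residual$category == "unannotated", ,
                               drop = FALSE]
    attr(residual, "libs") <- libs
    class(residual) <- class(known$residual)
    novel <- predict_novel(residual, config$genome,
                           flank_up = config$flank_up,
                           flank_down = config$flank_down,
                           max_loci = config$max_loci,
                           engine = config$engine,
                           min_mature_reads = config$min_mature_reads,
                           mfei_min = config$mfei_min)
    write_tsv(novel$calls, out("novel_calls.tsv"))
    reports <- unlist(lapply(novel$details, function(d)
      c(format_hairpin_report(d$call, d$locus), "")))
    writeLines(reports %||% character(0), out("novel_reports.txt"))
  }
  accepted <- novel$calls[novel$calls$accepted, , drop = FALSE]
  accepted <- accepted[!duplicated(accepted$tag_seq), , drop = FALSE]
  if (nrow(accepted))
    accepted$mirna_id <- sprintf("novel_mir_%d", seq_len(nrow(accepted)))
  manifest$novel <- list(evaluated_loci = nrow(novel$calls),
                         accepted = nrow(accepted))

  ## stage 4: differential expression ----------------------------------
  de_in <- rbind(
    if (nrow(known$hits))
      data.frame(mirna_id = known$hits$mirna_id, seq = known$hits$tag_seq,
                 x = known$hits$MS, y = known$hits$MF,
                 stringsAsFactors = FALSE),
    if (nrow(accepted))
      data.frame(mirna_id = accepted$mirna_id, seq = accepted$tag_seq,
                 x = accepted$MS, y = accepted$MF, stringsAsFactors = FALSE))
  if (is.null(de_in))
    de_in <- data.frame(mirna_id = character(0), seq = character(0),
                        x = integer(0), y = integer(0))
  de <- de_classify(de_in$mirna_id, de_in$x, de_in$y, N1, N2,
                    alpha = config$alpha, high_band = config$high_band,
                    low_band = config$low_band)
  de$seq <- de_in$seq
  write_tsv(de, out("de.tsv"))
  scatter <- data.frame(mirna_id = de$mirna_id, log2_MS = log2(de$nx),
                        log2_MF = log2(de$ny), de_class = de$de_class,
                        specificity = de$specificity)
  write_tsv(scatter, out("scatter.tsv"))
  manifest$diffexpr <- list(tested = nrow(de), de = sum(de$de),
                            ms_only = sum(de$specificity == "MS_only"),
                            mf_only = sum(de$specificity == "MF_only"))

  ## stages 5-6: targets and degradome ---------------------------------
  if (!is.null(config$transcripts)) {
    mirnas <- setNames(de$seq, de$mirna_id)
    mirnas <- mirnas[!duplicated(names(mirnas))]
    hits <- scan_targets(mirnas, config$transcripts)
    write_tsv(hits, out("targets.tsv"))
    manifest$targets <- list(mirnas = length(mirnas), sites = nrow(hits))
    if (!is.null(config$degradome)) {
      profiles <- build_profiles(config$degradome, config$transcripts)
      calls <- call_sites(mirnas, config$transcripts, profiles,
                          n_perm = config$n_perm, seed = config$seed,
                          alpha = config$alpha, hits = hits)
      write_tsv(calls, out("cleavage.tsv"))
      tp <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
        t <- tplot(profiles[[calls$transcript_id[i]]], calls[i, ])
        cbind(call = i, transcript_id = t$transcript_id, t$data,
              cleavage_pos = t$cleavage_pos)
      }))
      if (is.null(tp))
        tp <- data.frame(call = integer(0), transcript_id = character(0),
                         position = integer(0), count = integer(0),
                         cleavage_pos = integer(0))
      write_tsv(tp, out("tplots.tsv"))
      manifest$degradome <- list(
        profiles = length(profiles),
        mapped_tags = sum(vapply(profiles, `[[`, integer(1), "total_tags")),
        calls = nrow(calls))
    }
  }

  cfg_out <- unclass(config)
  jsonlite::write_json(cfg_out[!vapply(cfg_out, is.null, logical(1))],
                       out("effective_config.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  res <- list(tags = tags, known = known, novel = novel, de = de,
              manifest = manifest, outdir = outdir)
  if (exists("hits", inherits = FALSE)) res$targets <- hits
  if (exists("calls", inherits = FALSE)) res$cleavage <- calls
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_result>\n")
  cat(sprintf("  clean reads: MS %d, MF %d; unique tags %d\n",
              m$preprocess$clean_MS, m$preprocess$clean_MF,
              m$preprocess$unique_tags))
  cat(sprintf("  known miRNA hits %d; novel accepted %d; DE %d\n",
              m$known$hits, m$novel$accepted, m$diffexpr$de))
  if (!is.null(m$degradome))
    cat(sprintf("  cleavage calls %d\n", m$degradome$calls))
  invisible(x)
}
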