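#' Read paired FASTQ files (or one interleaved file)
#'
#' @param r1 path to the R1 FASTQ (or the interleaved file); plain or gzip.
#' @param r2 path to the R2 FASTQ; ignored when `interleaved = TRUE`.
#' @param interleaved logical; if TRUE, `r1` holds alternating mate-1/mate-2
#'   records. An odd trailing record becomes an orphan (counted in
#'   `all_bases`, never in `mt_bases`).
#' @return list with `ids`, `r1`, `r2` (character vectors, pair order as in
#'   the files) and `orphans`.
#' @export
read_fastq_pairs <- function(r1, r2 = NULL, interleaved = FALSE) {
  if (interleaved) {
    all <- read_fastq_file(r1)
    n <- length(all$seq)
    np <- n %/% 2L
    odd <- seq_len(np) * 2L - 1L
    orphans <- if (n %% 2L == 1L) all$seq[n] else character(0)
    return(list(ids = strip_mate_suffix(all$id[odd]),
                r1 = all$seq[odd], r2 = all$seq[odd + 1L], orphans = orphans))
  }
  if (is.null(r2))
    mc_stop("mitocount_input_error", "r2 is required unless interleaved = TRUE")
  a <- read_fastq_file(r1)
  b <- read_fastq_file(r2)
  if (length(a$seq) != length(b$seq))
    mc_stop("mitocount_format_error",
            "R1/R2 record counts differ (%d vs %d): first unmatched record is %d",
            length(a$seq), length(b$seq), min(length(a$seq), length(b$seq)) + 1L)
  list(ids = strip_mate_suffix(a$id), r1 = a$seq, r2 = b$seq,
       orphans = character(0))
}

read_fastq_file <- function(path) {
  if (!file.exists(path))
    mc_stop("mitocount_input_error", "FASTQ file not found: %s", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                   error = function(e)
                     mc_stop("mitocount_format_error", "malformed FASTQ %s: %s",
                             path, conditionMessage(e)))
  list(id = unname(sub("\\s.*$", "", names(seqs))), seq = unname(as.character(seqs)))
}

strip_mate_suffix <- function(ids) sub("/[12]$", "", ids)

run_csv_header <- c("run_id", "total_reads", "mito_reads", "all_bases",
                    "mt_bases", "mt_ratio")

#' Write the per-run counts CSV
#'
#' One row per run with the frozen header
#' `run_id,total_reads,mito_reads,all_bases,mt_bases,mt_ratio`; integers
#' unformatted, the ratio as a decimal fraction with 6 significant digits.
#'
#' @param counts non-empty list of `run_count` objects.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_run_csv <- function(counts, path) {
  if (length(counts) == 0)
    mc_stop("mitocount_input_error", "write_run_csv requires at least one run")
  if (inherits(counts, "run_count")) counts <- list(counts)
  df <- data.frame(
    run_id = vapply(counts, function(r) r$run_id, character(1)),
    total_reads = vapply(counts, function(r) as.numeric(r$total_reads), numeric(1)),
    mito_reads = vapply(counts, function(r) as.numeric(r$mito_reads), numeric(1)),
    all_bases = vapply(counts, function(r) as.numeric(r$all_bases), numeric(1)),
    mt_bases = vapply(counts, function(r) as.numeric(r$mt_bases), numeric(1)),
    stringsAsFactors = FALSE)
  df$mt_ratio <- vapply(ifelse(df$all_bases > 0, df$mt_bases / df$all_bases, 0),
                        function(r) format(signif(r, 6), scientific = FALSE, trim = TRUE),
                        character(1))
  for (col in c("total_reads", "mito_reads", "all_bases", "mt_bases"))
    df[[col]] <- vapply(df[[col]], format, character(1), scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-run counts CSV back into `run_count` objects
#'
#' @param path CSV written by [write_run_csv()].
#' @return list of `run_count` objects.
#' @export
read_run_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(run_csv_header, names(df))
  if (length(missing))
    mc_stop("mitocount_format_error", "run CSV %s lacks columns: %s", path,
            paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    structure(list(run_id = as.character(df$run_id[i]),
                   total_reads = df$total_reads[i],
                   mito_reads = df$mito_reads[i],
                   all_bases = df$all_bases[i],
                   mt_bases = df$mt_bases[i]),
              class = "run_count"))
}

#' Manifest of sequencing runs for one sample
#'
#' @param sample_id sample label.
#' @param runs data.frame with columns `run_id`, `r1`, `r2` (file paths).
#' @param check_files verify that every listed file exists. Default TRUE.
#' @return a `run_manifest` object.
#' @export
run_manifest <- function(sample_id, runs, check_files = TRUE) {
  if (!is.data.frame(runs) || nrow(runs) == 0)
    mc_stop("mitocount_input_error", "manifest for %s lists no runs", sample_id)
  stopifnot(all(c("run_id", "r1", "r2") %in% names(runs)))
  if (anyDuplicated(runs$run_id))
    mc_stop("mitocount_input_error", "duplicate run_id in manifest for %s", sample_id)
  if (check_files) {
    paths <- c(runs$r1, runs$r2)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      mc_stop("mitocount_input_error", "manifest file missing: %s", absent[1])
  }
  structure(list(sample_id = sample_id, runs = runs), class = "run_manifest")
}

#' Run the full three-stage assay
#'
#' Executes typing (anchor selection + guided assembly over the pooled
#' reads), per-run counting, and copy-number estimation; writes the consensus
#' FASTA with sidecar report, the per-run CSV and a one-row sample summary
#' CSV (`sample,runs,all_bases,mt_bases,mt_ratio,k`).
#'
#' @param manifest a [run_manifest()].
#' @param reference_path single-record mtDNA FASTA.
#' @param out_dir output directory (created if missing).
#' @param typing a [typing_params()].
#' @param pairing a [pairing_params()].
#' @param N haploid nuclear genome base count for [genome_params()]; M is
#'   taken from the typed consensus length.
#' @param ploidy_factor nuclear ploidy. Default 2.
#' @param verbose log per-stage progress to standard error. Default TRUE.
#' @return list with `consensus`, `counts`, `estimate` and `paths`.
#' @export
run_pipeline <- function(manifest, reference_path, out_dir,
                         typing = typing_params(), pairing = pairing_params(),
                         N, ploidy_factor = 2L, verbose = TRUE) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, mitocount_error = function(e) {
      mc_stop("mitocount_stage_error", "[%s] %s", name, conditionMessage(e))
    })
  }

  reference <- stage("type", read_reference_fasta(reference_path))
  log_msg("[type] reference %s: %d bp", reference$id, reference$length)
  runs <- lapply(seq_len(nrow(manifest$runs)), function(i)
    stage("count", read_fastq_pairs(manifest$runs$r1[i], manifest$runs$r2[i])))
  pool <- c(unlist(lapply(runs, `[[`, "r1")), unlist(lapply(runs, `[[`, "r2")))
  log_msg("[type] pooled %d reads from %d run(s)", length(pool), length(runs))

  consensus <- stage("type", type_consensus(pool, reference, typing))
  log_msg("[type] consensus %d bp, mean support %.1fx",
          consensus$length_bp, mean(consensus$per_base_support))
  consensus_paths <- write_consensus_fasta(consensus, reference,
                                           file.path(out_dir, manifest$sample_id),
                                           sample_id = manifest$sample_id)

  index <- build_index(consensus, pairing$seed_length)
  counts <- lapply(seq_along(runs), function(i) {
    rc <- stage("count", count_run(runs[[i]], index, pairing,
                                   run_id = manifest$runs$run_id[i]))
    log_msg("[count] run %s: %d/%d reads mitochondrial", rc$run_id,
            rc$mito_reads, rc$total_reads)
    rc
  })
  runs_csv <- file.path(out_dir, paste0(manifest$sample_id, "_runs.csv"))
  write_run_csv(counts, runs_csv)

  gp <- genome_params(N = N, M = consensus$length_bp, ploidy_factor = ploidy_factor)
  estimate <- stage("estimate", aggregate_runs(counts, gp))
  log_msg("[estimate] k = %.2f over %d run(s)", estimate$k, length(counts))
  summary_csv <- file.path(out_dir, paste0(manifest$sample_id, "_summary.csv"))
  write_sample_summary(manifest$sample_id, estimate, summary_csv)

  list(consensus = consensus, counts = counts, estimate = estimate,
       paths = list(consensus = unname(consensus_paths["fasta"]),
                    report = unname(consensus_paths["report"]),
                    runs_csv = runs_csv, summary_csv = summary_csv))
}

write_sample_summary <- function(sample_id, estimate, path) {
  df <- data.frame(sample = sample_id,
                   runs = length(estimate$per_run_ratios),
                   all_bases = estimate$pooled_all_bases,
                   mt_bases = estimate$pooled_mt_bases,
                   mt_ratio = format(signif(estimate$pooled_mt_bases /
                                              estimate$pooled_all_bases, 6),
                                     scientific = FALSE, trim = TRUE),
                   k = sprintf("%.2f", estimate$k))
  for (col in c("runs", "all_bases", "mt_bases"))
    df[[col]] <- vapply(df[[col]], format, character(1), scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
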