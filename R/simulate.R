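#' Specification of a synthetic paired-end WGS dataset
#'
#' Describes a desk-scale whole-genome sequencing experiment over a diploid
#' nuclear genome plus a circular mitochondrial genome present at `true_k`
#' copies per cell. Each read pair originates from the mitochondrial genome
#' with probability `true_k * M / (2N + true_k * M)` — the base-proportional
#' sampling premise of the copy-number estimator. Defaults mirror the
#' conditions used for end-to-end validation: a 2 Mbp haploid nuclear stand-in
#' (the estimator consumes only base-count ratios, so nuclear realism is not
#' needed), a 16,569 bp mitochondrial genome at 650 copies, 100 bp reads with
#' 300 +/- 30 bp inserts and 1% substitution error.
#'
#' @param nuclear_length haploid nuclear genome length N (bp).
#' @param mito_length mitochondrial genome length M (bp).
#' @param true_k planted mtDNA copy number (> 0).
#' @param read_length read length (bp).
#' @param n_pairs number of read pairs.
#' @param insert_mean,insert_sd normal insert-size parameters (bp); inserts
#'   are truncated to `[read_length, 4 * insert_mean]`.
#' @param error_rate per-base substitution probability in `[0, 0.5)`.
#' @param mito_divergence substitutions planted between the reference mtDNA
#'   and the sample's true mtDNA.
#' @param heteroplasmy_fraction minor-haplotype fraction in `[0, 0.5)`; when
#'   positive, a second mtDNA haplotype differing at one extra site supplies
#'   this fraction of mitochondrial fragments.
#' @param numt_length if positive, a copy of that many mitochondrial bases is
#'   planted inside the nuclear sequence (a synthetic NUMT) to exercise the
#'   documented misclassification bias. Default 0.
#' @param seed RNG seed (integer); all randomness derives from it.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(nuclear_length = 2e6, mito_length = 16569, true_k = 650,
                     read_length = 100, n_pairs = 2e5, insert_mean = 300,
                     insert_sd = 30, error_rate = 0.01, mito_divergence = 20,
                     heteroplasmy_fraction = 0, numt_length = 0, seed = 1L) {
  stopifnot(nuclear_length > 0, mito_length > 0, true_k > 0, read_length > 0,
            n_pairs >= 0, insert_mean >= read_length, insert_sd >= 0,
            error_rate >= 0, error_rate < 0.5, mito_divergence >= 0,
            heteroplasmy_fraction >= 0, heteroplasmy_fraction < 0.5,
            numt_length >= 0)
  if (mito_divergence > mito_length)
    mc_stop("mitocount_param_error",
            "mito_divergence (%d) exceeds mito_length (%d)",
            mito_divergence, mito_length)
  structure(list(nuclear_length = as.integer(nuclear_length),
                 mito_length = as.integer(mito_length),
                 true_k = as.numeric(true_k),
                 read_length = as.integer(read_length),
                 n_pairs = as.integer(n_pairs),
                 insert_mean = as.numeric(insert_mean),
                 insert_sd = as.numeric(insert_sd),
                 error_rate = as.numeric(error_rate),
                 mito_divergence = as.integer(mito_divergence),
                 heteroplasmy_fraction = as.numeric(heteroplasmy_fraction),
                 numt_length = as.integer(numt_length),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute positions of a sequence string with a different base each
plant_substitutions <- function(sequence, positions) {
  if (length(positions) == 0) return(sequence)
  bases <- c("A", "C", "G", "T")
  old <- substring(sequence, positions, positions)
  shift <- sample(1:3, length(positions), replace = TRUE)
  new <- bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
  for (i in seq_along(positions))
    substr(sequence, positions[i], positions[i]) <- new[i]
  sequence
}

#' Generate the synthetic genomes
#'
#' Draws an i.i.d. uniform nuclear sequence and a random circular reference
#' mtDNA, then plants `mito_divergence` substitutions to obtain the sample's
#' true mtDNA (and, if requested, one further substitution defining a minor
#' heteroplasmic haplotype, and a NUMT copy inside the nuclear sequence).
#'
#' @param spec a [sim_spec()].
#' @return list with `nuclear`, `mito_true`, `mito_ref` (strings),
#'   `variant_positions` (1-based), and `het` (NULL or
#'   `list(position, minor_base, minor_seq)`).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  nuclear <- random_dna(spec$nuclear_length)
  mito_ref <- random_dna(spec$mito_length)
  positions <- sort(sample(spec$mito_length, spec$mito_divergence))
  mito_true <- plant_substitutions(mito_ref, positions)
  het <- NULL
  if (spec$heteroplasmy_fraction > 0) {
    free <- setdiff(seq_len(spec$mito_length), positions)
    hp <- sample(free, 1)
    minor <- plant_substitutions(mito_true, hp)
    het <- list(position = hp, minor_base = substring(minor, hp, hp),
                minor_seq = minor)
  }
  if (spec$numt_length > 0) {
    if (spec$numt_length > spec$mito_length || spec$numt_length > spec$nuclear_length)
      mc_stop("mitocount_param_error", "numt_length exceeds a genome length")
    src <- sample(spec$mito_length - spec$numt_length + 1L, 1)
    dst <- sample(spec$nuclear_length - spec$numt_length + 1L, 1)
    substr(nuclear, dst, dst + spec$numt_length - 1L) <-
      substring(mito_true, src, src + spec$numt_length - 1L)
  }
  list(nuclear = nuclear, mito_true = mito_true, mito_ref = mito_ref,
       variant_positions = positions, het = het)
}

# vectorized per-base substitution errors (exact Bernoulli per base)
apply_errors <- function(reads, rate, chunk = 20000L) {
  if (rate == 0 || length(reads) == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  n <- length(reads)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    lens <- nchar(reads[lo:hi])
    L <- max(lens)
    hit <- which(matrix(runif(L * (hi - lo + 1L)) < rate, nrow = L))
    if (length(hit) == 0) next
    ri <- ((hit - 1L) %/% L) + lo
    pj <- ((hit - 1L) %% L) + 1L
    keep <- pj <= nchar(reads[ri])
    ri <- ri[keep]; pj <- pj[keep]
    if (length(ri) == 0) next
    old <- substring(reads[ri], pj, pj)
    shift <- sample(1:3, length(ri), replace = TRUE)
    new <- bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
    new[is.na(new)] <- "N"  # leave non-ACGT input bases alone, defensively
    for (e in seq_along(ri))
      substr(reads[ri[e]], pj[e], pj[e]) <- new[e]
  }
  reads
}

#' Simulate paired-end reads with truth labels
#'
#' Each pair's origin is mitochondrial with probability
#' `true_k * M / (2N + true_k * M)`. Fragment starts are uniform — circular
#' on the mitochondrial genome, linear on the nuclear one — mates read inward
#' from the fragment ends, either mate serving as R1 with equal probability,
#' and substitution errors are applied per base at `error_rate`.
#'
#' @param spec a [sim_spec()].
#' @param genome the triple from [simulate_genome()].
#' @return list with `ids`, `r1`, `r2` (character vectors) and `truth`
#'   (data.frame `pair_id`, `origin`, `start` (0-based fragment start on the
#'   source molecule), `insert`, `haplotype`).
#' @export
simulate_reads <- function(spec, genome) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_pairs
  L <- spec$read_length
  M <- spec$mito_length
  N <- spec$nuclear_length
  insert_cap <- as.integer(4 * spec$insert_mean)
  if (insert_cap > N)
    mc_stop("mitocount_param_error",
            "maximum insert (%d) exceeds the nuclear molecule (%d bp)",
            insert_cap, N)

  p_mito <- spec$true_k * M / (2 * N + spec$true_k * M)
  is_mito <- runif(n) < p_mito
  inserts <- as.integer(pmin(pmax(round(rnorm(n, spec$insert_mean, spec$insert_sd)), L),
                             insert_cap))
  # mitochondrial fragments may not wrap the full circle
  inserts[is_mito] <- pmin(inserts[is_mito], M)

  start <- integer(n)
  start[is_mito] <- sample.int(M, sum(is_mito), replace = TRUE) - 1L
  nn <- sum(!is_mito)
  start[!is_mito] <- as.integer(floor(runif(nn) * (N - inserts[!is_mito] + 1)))

  haplotype <- rep("major", n)
  if (!is.null(genome$het) && spec$heteroplasmy_fraction > 0)
    haplotype[is_mito & runif(n) < spec$heteroplasmy_fraction] <- "minor"

  # doubled mitochondrial strings make circular extraction a plain substring
  mito_ext <- paste0(genome$mito_true, genome$mito_true)
  frag <- character(n)
  idx <- which(is_mito & haplotype == "major")
  frag[idx] <- substring(mito_ext, start[idx] + 1L, start[idx] + inserts[idx])
  if (!is.null(genome$het)) {
    minor_ext <- paste0(genome$het$minor_seq, genome$het$minor_seq)
    idx <- which(is_mito & haplotype == "minor")
    frag[idx] <- substring(minor_ext, start[idx] + 1L, start[idx] + inserts[idx])
  }
  idx <- which(!is_mito)
  frag[idx] <- substring(genome$nuclear, start[idx] + 1L, start[idx] + inserts[idx])

  left <- substring(frag, 1L, L)
  right <- revcomp(substring(frag, inserts - L + 1L, inserts))
  flip <- runif(n) < 0.5
  r1 <- ifelse(flip, right, left)
  r2 <- ifelse(flip, left, right)
  r1 <- apply_errors(r1, spec$error_rate)
  r2 <- apply_errors(r2, spec$error_rate)

  ids <- sprintf("pair%07d", seq_len(n))
  truth <- data.frame(pair_id = ids,
                      origin = ifelse(is_mito, "mitochondrial", "nuclear"),
                      start = start, insert = inserts, haplotype = haplotype,
                      stringsAsFactors = FALSE)
  list(ids = ids, r1 = r1, r2 = r2, truth = truth)
}

#' Simulate a dataset and write it to disk
#'
#' Writes gzipped R1/R2 FASTQ, the reference mtDNA FASTA, a truth-label TSV
#' (`pair_id`, `origin`, `start`, `insert`, `haplotype`) and a JSON record of
#' the generator parameters.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix. Default `"sim"`.
#' @return invisibly, a named list of the written paths plus the in-memory
#'   `genome` and `reads`.
#' @export
simulate_dataset <- function(spec, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(spec)
  reads <- simulate_reads(spec, genome)
  paths <- list(r1 = file.path(dir, paste0(prefix, "_R1.fastq.gz")),
                r2 = file.path(dir, paste0(prefix, "_R2.fastq.gz")),
                reference = file.path(dir, paste0(prefix, "_reference.fasta")),
                truth = file.path(dir, paste0(prefix, "_truth.tsv")),
                spec = file.path(dir, paste0(prefix, "_spec.json")))
  write_fastq(paste0(reads$ids, "/1"), reads$r1, paths$r1)
  write_fastq(paste0(reads$ids, "/2"), reads$r2, paths$r2)
  writeLines(c(">reference_mito", genome$mito_ref), paths$reference)
  utils::write.table(reads$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(spec), paths$spec, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(genome = genome, reads = reads)))
}

# constant-quality FASTQ writer; gzip chosen by the .gz suffix
write_fastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
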