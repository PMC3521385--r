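#' Reference mitochondrial genome
#'
#' Light container for the guide sequence used by anchor selection and
#' assembly. The sequence is treated as circular.
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @param id text label.
#' @return a `mito_reference` object.
#' @export
mito_reference <- function(sequence, id = "reference") {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1 || nchar(sequence) == 0)
    mc_stop("mitocount_input_error", "reference sequence must be a single non-empty string")
  if (!is_dna(sequence))
    mc_stop("mitocount_input_error", "reference sequence contains characters outside A/C/G/T/N")
  structure(list(id = as.character(id), sequence = sequence,
                 length = nchar(sequence), circular = TRUE),
            class = "mito_reference")
}

#' Read a reference mitochondrial genome from FASTA
#'
#' @param path FASTA file with exactly one record (plain or gzip).
#' @return a [mito_reference()] object.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1)
    mc_stop("mitocount_input_error",
            "reference FASTA must contain exactly 1 record, found %d", length(seqs))
  mito_reference(as.character(seqs[[1]]), id = sub("\\s.*$", "", names(seqs)[1]))
}

#' Select beginning and ending anchor reads
#'
#' Maps the read pool (both orientations, error-tolerantly) against the
#' circular reference and selects two anchors: the beginning read, whose
#' placement starts within the reference start window `[0, anchor_window)`,
#' and the ending read, whose placement end lies within `anchor_window`
#' bases upstream of the beginning anchor on the circle — so that greedy
#' rightward extension from the beginning read traverses the whole circle
#' once before meeting the ending read. "Best" means fewest mismatches at
#' the anchoring placement; ties resolve to the earliest read in input
#' order, forward orientation before reverse.
#'
#' @param reads character vector of read sequences (the whole WGS pool),
#'   optionally named with read ids.
#' @param reference a [mito_reference()].
#' @param params a [typing_params()]; `anchor_tolerance` bounds the accepted
#'   mismatch fraction and `anchor_window` the window width.
#' @return an `anchor_reads` object with `beginning`, `ending` (each holding
#'   `id`, `sequence` in reference orientation, `index`, `orientation`,
#'   `mismatches`), `begin_offset` and `end_offset` (0-based reference
#'   positions where each anchor read starts).
#' @export
select_anchor_reads <- function(reads, reference, params = typing_params()) {
  if (length(reads) == 0)
    mc_stop("mitocount_input_error", "read pool is empty")
  stopifnot(inherits(reference, "mito_reference"))
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  reads <- as.character(reads)
  ref_index <- build_index(reference, min(31L, params$min_overlap, reference$length))

  pick <- function(begin_pos, label) {
    hit <- cpp_select_anchor(ref_index$ptr, reads, params$anchor_tolerance,
                             1L, params$anchor_window, begin_pos)
    if (hit$index == 0)
      mc_stop("mitocount_anchor_error",
              "insufficient mitochondrial coverage: no read matches the %s anchor window within tolerance",
              label)
    i <- hit$index
    seq_i <- if (hit$orientation == 0L) reads[i] else revcomp(reads[i])
    list(id = ids[i], sequence = toupper(seq_i), index = i,
         orientation = hit$orientation, position = hit$position,
         mismatches = hit$mismatches)
  }

  beginning <- pick(-1L, "beginning")
  ending <- pick(beginning$position, "ending")
  structure(list(beginning = beginning, ending = ending,
                 begin_offset = beginning$position,
                 end_offset = ending$position,
                 reference_length = reference$length),
            class = "anchor_reads")
}

#' Assemble the homoplasmic mtDNA consensus by guided greedy extension
#'
#' Starting from the beginning anchor, the contig is extended rightward: at
#' each step the candidate read with the longest verified overlap against the
#' contig tail wins (ties: fewest overlap mismatches, then input order,
#' forward orientation before reverse). The circle closes when the ending
#' anchor aligns flush with the contig tail at a total length within
#' `length_tol` of the reference length; assembly then continues `overhang`
#' extra bases so reads spanning the origin vote on the consensus start. The
#' per-position consensus base is the majority over all incorporated reads
#' (ties resolve alphabetically; N bases never vote).
#'
#' @param reads character vector of read sequences (same pool given to
#'   [select_anchor_reads()], same order).
#' @param anchors an `anchor_reads` object.
#' @param reference a [mito_reference()].
#' @param params a [typing_params()].
#' @return a `mito_consensus` object with `sequence`, `length_bp` and
#'   `per_base_support` (integer coverage of the majority vote at each
#'   position).
#' @export
assemble_consensus <- function(reads, anchors, reference, params = typing_params()) {
  stopifnot(inherits(anchors, "anchor_reads"), inherits(reference, "mito_reference"))
  reads <- as.character(reads)
  M <- reference$length
  # one full traversal of the circle from the beginning anchor back to
  # itself; the junction self-alignment pins the exact length within
  # [target - length_tol, target + length_tol]
  target <- M
  max_length <- as.integer(params$max_length %||% (M + 5000L))
  overhang <- as.integer(params$overhang %||% max(nchar(reads)))

  res <- cpp_assemble(reads,
                      begin_pool = 2L * (anchors$beginning$index - 1L) + anchors$beginning$orientation,
                      end_pool = 2L * (anchors$ending$index - 1L) + anchors$ending$orientation,
                      min_overlap = params$min_overlap,
                      max_mm_rate = params$max_mismatch_rate,
                      max_length = max_length,
                      target_len = as.integer(target),
                      len_tol = params$length_tol,
                      overhang = overhang)
  if (res$status == "gap")
    mc_stop("mitocount_gap_error",
            "assembly gap: extension stalled at contig position %d (no candidate with overlap >= %d)",
            res$stall, params$min_overlap, data = list(stall = res$stall))
  if (res$status == "runaway")
    mc_stop("mitocount_runaway_error",
            "runaway assembly: contig exceeded %d bp without meeting the ending read",
            max_length)
  if (grepl("N", res$sequence, fixed = TRUE))
    mc_stop("mitocount_assembly_error",
            "consensus contains unresolved (all-N) columns")
  # linearize at the reference start coordinate: the contig begins at
  # reference position begin_offset, so rotate it left by Mc - begin_offset
  seq <- res$sequence
  support <- res$support
  b <- anchors$begin_offset %% res$length
  if (b > 0) {
    cut <- res$length - b
    seq <- paste0(substring(seq, cut + 1L, res$length), substring(seq, 1L, cut))
    support <- c(support[(cut + 1L):res$length], support[1:cut])
  }
  mito_consensus(seq, support, reads_used = res$reads_used)
}

mito_consensus <- function(sequence, support, reads_used = NA_integer_) {
  stopifnot(nchar(sequence) == length(support), all(support >= 1))
  structure(list(sequence = sequence, length_bp = nchar(sequence),
                 per_base_support = as.integer(support),
                 reads_used = reads_used),
            class = "mito_consensus")
}

#' @export
print.mito_consensus <- function(x, ...) {
  cat(sprintf("mito_consensus: %d bp, mean support %.1fx (%s reads incorporated)\n",
              x$length_bp, mean(x$per_base_support),
              format(x$reads_used)))
  invisible(x)
}

#' Type a sample's mtDNA consensus from a read pool
#'
#' Convenience wrapper: [select_anchor_reads()] then [assemble_consensus()].
#'
#' @inheritParams select_anchor_reads
#' @return a `mito_consensus`.
#' @export
type_consensus <- function(reads, reference, params = typing_params()) {
  anchors <- select_anchor_reads(reads, reference, params)
  assemble_consensus(reads, anchors, reference, params)
}

#' Write a consensus FASTA plus sidecar report
#'
#' @param consensus a `mito_consensus`.
#' @param reference the guide [mito_reference()] (for the mismatch count in
#'   the report).
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.report.txt`.
#' @param sample_id header for the FASTA record.
#' @return invisibly, the two paths.
#' @export
write_consensus_fasta <- function(consensus, reference, prefix, sample_id = "sample") {
  fa <- paste0(prefix, ".fasta")
  rp <- paste0(prefix, ".report.txt")
  writeLines(c(paste0(">", sample_id), consensus$sequence), fa)
  n_mm <- consensus_reference_mismatches(consensus, reference)
  writeLines(c(sprintf("sample_id\t%s", sample_id),
               sprintf("length_bp\t%d", consensus$length_bp),
               sprintf("reference_length_bp\t%d", reference$length),
               sprintf("mismatches_vs_reference\t%s", format(n_mm)),
               sprintf("mean_support\t%.4f", mean(consensus$per_base_support))),
             rp)
  invisible(c(fasta = fa, report = rp))
}

# positionwise mismatches vs the guide, only defined for equal lengths
consensus_reference_mismatches <- function(consensus, reference) {
  if (consensus$length_bp != reference$length) return(NA_integer_)
  a <- strsplit(consensus$sequence, "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(reference$sequence), "", fixed = TRUE)[[1]]
  sum(a != b)
}
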