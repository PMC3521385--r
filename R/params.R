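#' Typing (guided assembly) parameters
#'
#' Tuning knobs for anchor selection and greedy-overlap consensus assembly.
#'
#' @param min_overlap minimum read-to-contig overlap (bp) accepted during
#'   extension. Default 31, large enough to reject chance overlaps at
#'   ~100 bp read length.
#' @param max_mismatch_rate maximum mismatch fraction tolerated inside an
#'   overlap (and in the ending-read junction test). Default 0.05.
#' @param anchor_tolerance maximum mismatch fraction for a read to qualify as
#'   a beginning/ending anchor against the reference. Default 0.15, loose
#'   enough to absorb sample-vs-reference divergence plus sequencing error
#'   while still excluding unrelated reads.
#' @param anchor_window width (bp) of the reference start window within which
#'   the beginning read may anchor, and of the arc upstream of the beginning
#'   anchor within which the ending read must close the circle. Default 200.
#' @param max_length maximum assembly length (bp) before the run is declared
#'   a runaway; `NULL` means reference length + 5000.
#' @param length_tol half-width (bp) of the window around the reference
#'   length within which the ending read may close the circle. Default 500.
#' @param overhang extra bases assembled past the circle junction so reads
#'   spanning the origin contribute wrapped majority votes to the consensus
#'   start; `NULL` means the longest read length.
#' @return a `typing_params` list.
#' @export
typing_params <- function(min_overlap = 31L, max_mismatch_rate = 0.05,
                          anchor_tolerance = 0.15, anchor_window = 200L,
                          max_length = NULL, length_tol = 500L,
                          overhang = NULL) {
  stopifnot(min_overlap >= 8, max_mismatch_rate >= 0, max_mismatch_rate < 0.5,
            anchor_tolerance >= 0, anchor_tolerance < 0.5,
            anchor_window >= 1, length_tol >= 0)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 anchor_tolerance = anchor_tolerance,
                 anchor_window = as.integer(anchor_window),
                 max_length = max_length,
                 length_tol = as.integer(length_tol),
                 overhang = overhang),
            class = "typing_params")
}

#' Read-pair classification parameters
#'
#' Tuning knobs for the error-tolerant seed-and-verify mapper and the
#' paired-end concordance gate.
#'
#' @param seed_length k-mer seed length (bp), between 8 and 31. Default 15:
#'   short enough that a read needs many tightly clustered errors before no
#'   clean seed window survives, yet specific against a ~16.5 kb target.
#' @param stride spacing between seed offsets extracted from a read; the
#'   final window flush with the read end is always included. Default 1
#'   (every offset), which guarantees that any read with at least one
#'   error-free seed-length window is recovered by the index lookup.
#' @param max_mismatch_rate maximum mismatch fraction per read for a
#'   placement to be accepted (`floor(rate * read_length)` mismatches).
#'   Default 0.10: generous against the sequencing-error tail (a 100 bp read
#'   at 1% error exceeds 10 mismatches with probability ~1e-8) while still
#'   demanding 90% identity, far beyond any chance placement.
#' @param insert_min,insert_max accepted circular insert-size window (bp) for
#'   a concordant pair. Defaults 50 and 1000.
#' @return a `pairing_params` list.
#' @export
pairing_params <- function(seed_length = 15L, stride = 1L,
                           max_mismatch_rate = 0.10,
                           insert_min = 50L, insert_max = 1000L) {
  stopifnot(seed_length >= 8, seed_length <= 31, stride >= 1,
            max_mismatch_rate >= 0, max_mismatch_rate < 0.5,
            insert_min >= 1, insert_max >= insert_min)
  structure(list(seed_length = as.integer(seed_length),
                 stride = as.integer(stride),
                 max_mismatch_rate = max_mismatch_rate,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max)),
            class = "pairing_params")
}

#' Genome parameters for copy-number estimation
#'
#' @param N haploid nuclear genome base count (bp). The human value is not a
#'   universal constant of the method and must be supplied explicitly (or via
#'   [nuclear_size_from_fasta()]).
#' @param M mtDNA length (bp); normally the typed consensus length.
#' @param ploidy_factor nuclear ploidy, default 2 (diploid), so the nuclear
#'   complement contributes `ploidy_factor * N` bases per cell.
#' @return a `genome_params` list.
#' @export
genome_params <- function(N, M, ploidy_factor = 2L) {
  stopifnot(is.numeric(N), length(N) == 1, N > 0,
            is.numeric(M), length(M) == 1, M > 0,
            ploidy_factor >= 1)
  structure(list(N = as.numeric(N), M = as.numeric(M),
                 ploidy_factor = as.integer(ploidy_factor)),
            class = "genome_params")
}

#' Derive the haploid nuclear base count from a FASTA file
#'
#' Counts non-N bases across all records of a nuclear reference FASTA.
#'
#' @param path FASTA file (plain or gzip).
#' @return numeric scalar, total non-N bases.
#' @export
nuclear_size_from_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  freq <- Biostrings::alphabetFrequency(seqs)
  sum(freq[, c("A", "C", "G", "T"), drop = FALSE])
}
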