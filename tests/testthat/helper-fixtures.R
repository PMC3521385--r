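# Shared fixtures and independent oracles. Everything here is deliberately
# naive R / Biostrings so it shares no code path with the package internals
# it checks.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_oracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# circular substring extraction, 0-based start
circ_substr <- function(seq, start, len) {
  doubled <- paste0(seq, seq)
  substring(doubled, start + 1L, start + len)
}

# noiseless reads tiling a circular sequence at a fixed step (forward strand)
tile_reads <- function(seq, read_len = 100L, step = 50L) {
  starts <- seq(0L, nchar(seq) - 1L, by = step)
  vapply(starts, function(s) circ_substr(seq, s, read_len), character(1))
}

# plant substitutions at given 1-based positions, each to the "next" base
mutate_at <- function(seq, positions) {
  for (p in positions) {
    old <- substring(seq, p, p)
    substr(seq, p, p) <- BASES[(match(old, BASES) %% 4L) + 1L]
  }
  seq
}

# independent per-base noise injection (plain R, not the package generator)
add_noise <- function(reads, rate) {
  vapply(reads, function(r) {
    hits <- which(runif(nchar(r)) < rate)
    if (length(hits)) r <- mutate_at(r, hits)
    r
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive circular Hamming-distance scan over all positions and both
# strands, via Biostrings. Returns the same columns as map_read(), ordered by
# (mismatches, position, strand).
oracle_scan <- function(read, consensus, max_mm) {
  M <- nchar(consensus)
  L <- nchar(read)
  doubled <- Biostrings::DNAString(paste0(consensus, substring(consensus, 1, L - 1)))
  out <- data.frame(position = integer(0), strand = character(0),
                    mismatches = integer(0))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else rc_oracle(read)
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(s), doubled,
                                      starting.at = seq_len(M),
                                      with.indels = FALSE)
    hit <- which(mm <= max_mm)
    if (length(hit))
      out <- rbind(out, data.frame(position = hit - 1L, strand = strand,
                                   mismatches = mm[hit]))
  }
  out[order(out$mismatches, out$position, out$strand), , drop = FALSE]
}

# does at least one seed-length window of the read match its source
# placement error-free? (the condition under which oracle equivalence of the
# seeded mapper is guaranteed)
has_clean_window <- function(read, consensus, position, strand, seed_len) {
  L <- nchar(read)
  s <- if (strand == "+") read else rc_oracle(read)
  ref <- circ_substr(consensus, position, L)
  ok <- strsplit(s, "")[[1]] == strsplit(ref, "")[[1]]
  any(vapply(seq_len(L - seed_len + 1L),
             function(o) all(ok[o:(o + seed_len - 1L)]), logical(1)))
}

# build a noiseless concordant read pair from a circular molecule
make_pair <- function(seq, start, insert, read_len) {
  frag <- circ_substr(seq, start, insert)
  list(r1 = substring(frag, 1, read_len),
       r2 = rc_oracle(substring(frag, insert - read_len + 1, insert)))
}
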