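test_that("seed index covers all circular positions and answers lookups", {
  set.seed(11)
  cons <- rand_seq(2000)
  idx <- build_index(cons, seed_length = 31)
  expect_identical(index_size(idx), 2000L)          # one seed per position
  seed137 <- circ_substr(cons, 137, 31)
  expect_true(137L %in% index_lookup(idx, seed137))
  # a seed engineered to differ from every indexed window comes back empty
  absent <- mutate_at(seed137, c(5, 15, 25))
  hits <- index_lookup(idx, absent)
  expect_true(length(hits) == 0 ||
                !any(vapply(hits, function(p) circ_substr(cons, p, 31) == absent,
                            logical(1))))
  expect_error(build_index(cons, seed_length = 5), class = "mitocount_param_error")
  expect_error(build_index(cons, seed_length = 40), class = "mitocount_param_error")
})

test_that("map_read places exact, mutated and hopeless reads like the oracle", {
  set.seed(22)
  cons <- rand_seq(2000)
  idx <- build_index(cons, seed_length = 15)

  # exact substring: positions 100..199
  exact <- circ_substr(cons, 100, 100)
  hits <- map_read(exact, idx, max_mismatches = 5)
  expect_identical(hits$position[1], 100L)
  expect_identical(hits$strand[1], "+")
  expect_identical(hits$mismatches[1], 0L)

  # exactly max_mismatches substitutions (kept clear of the first window)
  # place; one more does not
  at_cap <- mutate_at(exact, c(30, 45, 60, 75, 90))
  over_cap <- mutate_at(exact, c(30, 45, 60, 75, 90, 95))
  expect_identical(map_read(at_cap, idx, 5)$position[1], 100L)
  expect_identical(nrow(map_read(over_cap, idx, 5)), 0L)
  expect_identical(oracle_scan(at_cap, cons, 5)$position[1], 100L)
  expect_identical(nrow(oracle_scan(over_cap, cons, 5)), 0L)

  # reverse-strand placement
  rev_hits <- map_read(rc_oracle(exact), idx, 5)
  expect_identical(rev_hits$position[1], 100L)
  expect_identical(rev_hits$strand[1], "-")

  # i.i.d. random reads find nothing (oracle agrees)
  for (i in 1:5) {
    r <- rand_seq(100)
    expect_identical(nrow(map_read(r, idx, 5)), nrow(oracle_scan(r, cons, 5)))
  }

  # a read shorter than the seed is unmappable, not an error
  expect_identical(nrow(map_read("ACGT", idx, 1)), 0L)
})

test_that("map_read equals the exhaustive circular scan whenever a clean seed window exists", {
  set.seed(33)
  cons <- rand_seq(2000)
  seed_len <- 15L
  idx <- build_index(cons, seed_length = seed_len)
  max_mm <- 8L
  n_checked <- 0L
  for (i in 1:60) {
    pos <- sample(0:1999, 1)
    strand <- sample(c("+", "-"), 1)
    src <- circ_substr(cons, pos, 100)
    if (strand == "-") src <- rc_oracle(src)
    read <- mutate_at(src, sample(100, sample(0:8, 1)))
    if (!has_clean_window(read, cons, pos, strand, seed_len)) next
    n_checked <- n_checked + 1L
    got <- map_read(read, idx, max_mm)
    want <- oracle_scan(read, cons, max_mm)
    expect_identical(got$position, want$position)
    expect_identical(got$mismatches, want$mismatches)
    expect_identical(got$strand, want$strand)
  }
  expect_gt(n_checked, 40)
})

test_that("pair classification applies the strand and circular-insert gates", {
  set.seed(44)
  cons <- rand_seq(2000)
  idx <- build_index(cons)
  params <- pairing_params(insert_min = 100, insert_max = 600)

  # concordant exact pair, insert 300
  p <- make_pair(cons, 150, 300, 100)
  v <- classify_pair(p$r1, p$r2, idx, params)
  expect_true(v$is_mito)
  expect_identical(v$insert_size, 300L)
  expect_identical(v$placements$position, c(150L, 350L))

  # heavily overlapping mates (insert shorter than two read lengths)
  p2 <- make_pair(cons, 900, 120, 100)
  v2 <- classify_pair(p2$r1, p2$r2, idx, params)
  expect_true(v2$is_mito)
  expect_identical(v2$insert_size, 120L)

  # an insert spanning the circle origin is measured on the wrapped arc
  p3 <- make_pair(cons, 1900, 300, 100)
  v3 <- classify_pair(p3$r1, p3$r2, idx, params)
  expect_true(v3$is_mito)
  expect_identical(v3$insert_size, 300L)

  # one mate random: no verdict of mitochondrial
  expect_false(classify_pair(p$r1, rand_seq(100), idx, params)$is_mito)

  # both mates map but the circular distance (900) misses [100, 600]; the
  # brute-force enumeration over all oracle placements agrees that no
  # concordant combination exists
  p4 <- make_pair(cons, 100, 900, 100)
  expect_false(classify_pair(p4$r1, p4$r2, idx, params)$is_mito)
  o1 <- oracle_scan(p4$r1, cons, 10)
  o2 <- oracle_scan(p4$r2, cons, 10)
  found <- FALSE
  for (a in seq_len(nrow(o1))) for (b in seq_len(nrow(o2))) {
    if (o1$strand[a] == o2$strand[b]) next
    pa <- if (o1$strand[a] == "+") o1$position[a] else o2$position[b]
    pb <- if (o1$strand[a] == "+") o2$position[b] else o1$position[a]
    d1 <- ((pb + 100 - pa) %% 2000 + 2000) %% 2000
    d2 <- ((pa + 100 - pb) %% 2000 + 2000) %% 2000
    if ((d1 >= 100 && d1 <= 600) || (d2 >= 100 && d2 <= 600)) found <- TRUE
  }
  expect_false(found)
})

test_that("verdicts are invariant under reverse-complementing and swapping mates", {
  set.seed(55)
  cons <- rand_seq(2000)
  idx <- build_index(cons)
  params <- pairing_params()
  for (i in 1:25) {
    if (i %% 5 == 0) {
      r1 <- rand_seq(100); r2 <- rand_seq(100)      # nuclear-like
    } else {
      p <- make_pair(cons, sample(0:1999, 1), sample(150:900, 1), 100)
      r1 <- p$r1; r2 <- p$r2
    }
    v <- classify_pair(r1, r2, idx, params)
    w <- classify_pair(rc_oracle(r2), rc_oracle(r1), idx, params)
    expect_identical(v$is_mito, w$is_mito)
    if (v$is_mito) expect_identical(v$insert_size, w$insert_size)
  }
})

test_that("count_run totals bases and respects conservation", {
  set.seed(66)
  cons <- rand_seq(2000)
  idx <- build_index(cons)
  params <- pairing_params()

  empty <- count_run(list(r1 = character(0), r2 = character(0)), idx, params)
  expect_identical(empty$total_reads, 0L)
  expect_identical(empty$mito_reads, 0L)
  expect_identical(empty$all_bases, 0L)
  expect_identical(empty$mt_bases, 0L)

  # 100 pairs, 37 planted mitochondrial, the rest random; truth labels are
  # the oracle
  mito_idx <- sample(100, 37)
  r1 <- character(100); r2 <- character(100)
  for (i in seq_len(100)) {
    if (i %in% mito_idx) {
      p <- make_pair(cons, sample(0:1999, 1), 300, 100)
      r1[i] <- p$r1; r2[i] <- p$r2
    } else {
      r1[i] <- rand_seq(100); r2[i] <- rand_seq(100)
    }
  }
  rc <- count_run(list(r1 = r1, r2 = r2), idx, params, run_id = "planted")
  expect_identical(rc$mito_reads, 74L)
  expect_identical(rc$mt_bases, 74L * 100L)
  expect_identical(rc$total_reads, 200L)
  expect_lte(rc$mt_bases, rc$all_bases)

  # saturation: every pair mitochondrial
  sat <- count_run(list(r1 = r1[mito_idx], r2 = r2[mito_idx]), idx, params)
  expect_identical(sat$mt_bases, sat$all_bases)

  # orphans count toward all_bases but never mt_bases
  orp <- count_run(list(r1 = r1[mito_idx], r2 = r2[mito_idx],
                        orphans = c(rand_seq(100), circ_substr(cons, 5, 100))),
                   idx, params)
  expect_identical(orp$all_bases, sat$all_bases + 200L)
  expect_identical(orp$mt_bases, sat$mt_bases)
  expect_identical(orp$total_reads, sat$total_reads + 2L)

  expect_error(count_run(list(r1 = r1, r2 = r2[-1]), idx, params, run_id = "bad"),
               "run bad")

  # summing per-run counts equals counting the concatenated stream
  rc_a <- count_run(list(r1 = r1[1:40], r2 = r2[1:40]), idx, params)
  rc_b <- count_run(list(r1 = r1[41:100], r2 = r2[41:100]), idx, params)
  expect_identical(rc_a$mt_bases + rc_b$mt_bases, rc$mt_bases)
  expect_identical(rc_a$all_bases + rc_b$all_bases, rc$all_bases)
})

test_that("pileup flags planted heteroplasmy and nothing else", {
  set.seed(77)
  cons <- rand_seq(2000)
  idx <- build_index(cons)
  params <- pairing_params()

  # homoplasmic noiseless coverage: no flagged site at threshold 0.1
  pairs <- lapply(1:500, function(i) make_pair(cons, sample(0:1999, 1), 300, 100))
  run <- list(r1 = vapply(pairs, `[[`, "", "r1"), r2 = vapply(pairs, `[[`, "", "r2"))
  rc <- count_run(run, idx, params, keep_verdicts = TRUE)
  pu <- pileup_alleles(attr(rc, "verdicts"), run, cons, min_minor_fraction = 0.1)
  expect_identical(nrow(pu$sites), 0L)
  expect_identical(sum(pu$counts), rc$mt_bases)

  # 20%/80% two-haplotype mixture differing at one site
  site <- 1000L                                    # 1-based
  minor <- mutate_at(cons, site)
  pairs2 <- lapply(1:800, function(i) {
    src <- if (runif(1) < 0.2) minor else cons
    make_pair(src, sample(0:1999, 1), 300, 100)
  })
  run2 <- list(r1 = vapply(pairs2, `[[`, "", "r1"), r2 = vapply(pairs2, `[[`, "", "r2"))
  rc2 <- count_run(run2, idx, params, keep_verdicts = TRUE)
  pu2 <- pileup_alleles(attr(rc2, "verdicts"), run2, cons, min_minor_fraction = 0.1)
  expect_identical(pu2$sites$position, site - 1L)
  cov <- pu2$sites$coverage
  sd3 <- 3 * sqrt(0.2 * 0.8 / cov)
  expect_lt(abs(pu2$sites$minor_fraction - 0.2), sd3)

  # threshold zero flags exactly the positions carrying any second allele
  pu0 <- pileup_alleles(attr(rc2, "verdicts"), run2, cons, min_minor_fraction = 0)
  second_allele <- which(colSums(pu2$counts > 0) > 1) - 1L
  expect_identical(pu0$sites$position, second_allele)
})
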