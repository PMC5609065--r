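# Read decoding, pool-based grouping, and conservation of input reads.

make_clean_pairs <- function(n, seed = 1) {
  set.seed(seed)
  idx <- matrix(sample(0:63, 6 * n, replace = TRUE), ncol = 6)
  pairs <- lapply(seq_len(n), function(i)
    render_read_pair(idx[i, ], random_dna_str(6), random_dna_str(6),
                     random_dna_str(80), random_dna_str(80)))
  list(idx = idx,
       seq1 = vapply(pairs, `[[`, character(1), "seq1"),
       seq2 = vapply(pairs, `[[`, character(1), "seq2"))
}

test_that("segments extracted at layout offsets round-trip the generator", {
  set.seed(3)
  idx <- sample(0:63, 6)
  rp <- render_read_pair(idx, "ACGTAC", "TTGGCA", strrep("AG", 40),
                         strrep("CT", 40))
  seg <- extract_segments(rp$seq1, rp$seq2, LAYOUT)
  expect_identical(seg$end1$randmer, "ACGTAC")
  expect_identical(seg$end2$randmer, "TTGGCA")
  expect_identical(seg$end1$subunits, CODE$barcodes[idx[1:3] + 1L])
  expect_identical(seg$end2$subunits, CODE$barcodes[idx[4:6] + 1L])
  expect_identical(seg$end1$insert, strrep("AG", 40))
  expect_identical(nchar(seg$end1$insert), 80L)
  expect_error(extract_segments(substr(rp$seq1, 1, 70), rp$seq2, LAYOUT),
               "shorter")
})

test_that("decoding tolerates one substitution per subunit and flags doubles", {
  cp <- make_clean_pairs(1, seed = 8)
  d0 <- decode_reads(cp$seq1, cp$seq2, CODE, LAYOUT)
  expect_identical(d0$status, "ok")
  true_key <- d0$key
  # one substitution inside subunit 2 of mate 1 (positions 23..28)
  mut <- substitute_base(cp$seq1, 25L)
  d1 <- decode_reads(mut, cp$seq2, CODE, LAYOUT)
  expect_identical(d1$status, "ok")
  expect_identical(d1$key, true_key)
  # two substitutions inside one subunit: ambiguous with 3 candidate keys
  mut2 <- substitute_base(mut, 26L)
  d2 <- decode_reads(mut2, cp$seq2, CODE, LAYOUT)
  expect_identical(d2$status, "ambiguous")
  expect_length(d2$cand_keys[[1]], 3L)
  expect_true(true_key %in% d2$cand_keys[[1]])
  # short mate is discarded with a reason
  d3 <- decode_reads(substr(cp$seq1, 1, 70), cp$seq2, CODE, LAYOUT)
  expect_identical(d3$status, "discard")
  expect_identical(d3$reason, "read_too_short")
})

test_that("error-free reads group one molecule per adapter", {
  cp <- make_clean_pairs(30, seed = 10)
  dec <- decode_reads(cp$seq1, cp$seq2, CODE, LAYOUT)
  gr <- group_reads(dec)
  expect_identical(nrow(gr$groups), 30L)
  expect_true(all(gr$groups$size == 1L))
  expect_identical(nrow(gr$discards), 0L)
})

test_that("a correctable subunit error keeps duplicates in one group", {
  cp <- make_clean_pairs(1, seed = 12)
  seq1 <- c(cp$seq1, cp$seq1, substitute_base(cp$seq1, 23L))
  seq2 <- rep(cp$seq2, 3)
  gr <- group_reads(decode_reads(seq1, seq2, CODE, LAYOUT))
  expect_identical(nrow(gr$groups), 1L)
  expect_identical(gr$groups$size, 3L)
})

test_that("pool resolution assigns, invents, or discards ambiguous reads", {
  cp <- make_clean_pairs(1, seed = 14)
  dec0 <- decode_reads(cp$seq1, cp$seq2, CODE, LAYOUT)
  true_key <- dec0$key
  amb1 <- substitute_base(substitute_base(cp$seq1, 7L), 9L)  # subunit 1 x2
  # case 1: truth in pool via a clean copy -> resolved to the pooled key
  gr1 <- group_reads(decode_reads(c(cp$seq1, amb1), rep(cp$seq2, 2),
                                  CODE, LAYOUT))
  expect_identical(nrow(gr1$groups), 1L)
  expect_identical(gr1$groups$key, true_key)
  expect_identical(gr1$groups$size, 2L)
  expect_identical(sort(gr1$assignments$how),
                   c("pool_resolved", "unambiguous"))
  # case 2: empty pool -> unique molecule under the smallest candidate
  dec2 <- decode_reads(amb1, cp$seq2, CODE, LAYOUT)
  gr2 <- group_reads(dec2)
  expect_identical(nrow(gr2$groups), 1L)
  expect_identical(gr2$groups$key, dec2$cand_keys[[1]][1])
  expect_identical(gr2$assignments$how, "novel_canonical")
  # case 3: several candidates in the pool -> discarded
  cands <- dec2$cand_keys[[1]]
  idx_of <- function(k) as.integer(strsplit(k, "-")[[1]])
  mk <- function(k) render_read_pair(idx_of(k), "AAAAAA", "CCCCCC",
                                     strrep("A", 80), strrep("C", 80))
  p1 <- mk(cands[1]); p2 <- mk(cands[2])
  gr3 <- group_reads(decode_reads(c(p1$seq1, p2$seq1, amb1),
                                  c(p1$seq2, p2$seq2, cp$seq2),
                                  CODE, LAYOUT))
  expect_identical(nrow(gr3$groups), 2L)
  expect_identical(gr3$discards$reason, "ambiguous_multi_pool")
})

test_that("every input read is either assigned or discarded with a reason", {
  set.seed(16)
  cfg <- sim_config(n_fragments = 40, depth = 400, cycles = 5,
                    e_seq = 0.01, seed = 16)
  sim <- simulate_library(cfg, CODE, LAYOUT)
  dec <- decode_reads(sim$reads$seq1, sim$reads$seq2, CODE, LAYOUT,
                      sim$reads$read_id)
  gr <- group_reads(dec)
  expect_identical(nrow(gr$assignments) + nrow(gr$discards), 400L)
  expect_identical(sum(gr$groups$size), nrow(gr$assignments))
  expect_false(any(gr$assignments$read_id %in% gr$discards$read_id))
})

test_that("grouping is invariant to input order", {
  cfg <- sim_config(n_fragments = 25, depth = 200, cycles = 5,
                    e_seq = 0.01, seed = 18)
  sim <- simulate_library(cfg, CODE, LAYOUT)
  dec <- decode_reads(sim$reads$seq1, sim$reads$seq2, CODE, LAYOUT,
                      sim$reads$read_id)
  gr_a <- group_reads(dec)
  set.seed(19)
  perm <- sample.int(nrow(dec))
  gr_b <- group_reads(dec[perm, ])
  ga <- gr_a$groups[, c("key", "size")]
  gb <- gr_b$groups[, c("key", "size")]
  expect_identical(ga, gb)
  for (k in gr_a$groups$key)
    expect_setequal(gr_a$groups$read_ids[[which(gr_a$groups$key == k)]],
                    gr_b$groups$read_ids[[which(gr_b$groups$key == k)]])
})

test_that("one substitution per read leaves grouping identical to zero noise", {
  cp <- make_clean_pairs(20, seed = 20)
  seq1 <- rep(cp$seq1, 2)  # two copies of each molecule
  seq2 <- rep(cp$seq2, 2)
  gr0 <- group_reads(decode_reads(seq1, seq2, CODE, LAYOUT))
  set.seed(21)
  subunit_starts <- c(7L, 23L, 38L)
  mut1 <- seq1
  for (i in seq_along(mut1)) {
    pos <- sample(subunit_starts, 1) + sample(0:5, 1)
    mut1[i] <- substitute_base(mut1[i], pos)
  }
  gr1 <- group_reads(decode_reads(mut1, seq2, CODE, LAYOUT))
  expect_identical(gr0$groups[, c("key", "size")],
                   gr1$groups[, c("key", "size")])
})

test_that("FASTQ input round-trips through the pair reader", {
  cp <- make_clean_pairs(5, seed = 22)
  tmp <- withr::local_tempdir()
  cfg <- sim_config(n_fragments = 5, depth = 20, cycles = 3, seed = 22)
  sim <- simulate_library(cfg, CODE, LAYOUT,
                          out_prefix = file.path(tmp, "lib"))
  rp <- read_fastq_pairs(file.path(tmp, "lib_R1.fastq.gz"),
                         file.path(tmp, "lib_R2.fastq.gz"))
  expect_identical(nrow(rp), 20L)
  expect_identical(rp$seq1, sim$reads$seq1)
  expect_identical(rp$seq2, sim$reads$seq2)
  expect_identical(rp$read_id, sim$reads$read_id)
})
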