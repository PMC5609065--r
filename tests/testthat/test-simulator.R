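# Library simulator: determinism, conservation, truth consistency, and
# agreement with the closed-form error models.

test_that("simulation is seed-deterministic and conserves read pairs", {
  cfg <- sim_config(n_fragments = 30, depth = 333, cycles = 5,
                    e_pcr = 1e-4, e_seq = 0.002, seed = 61)
  s1 <- simulate_library(cfg, CODE, LAYOUT)
  s2 <- simulate_library(cfg, CODE, LAYOUT)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$molecules, s2$truth$molecules)
  expect_identical(nrow(s1$reads), 333L)
  expect_true(all(s1$truth$reads$molecule_id %in%
                  s1$truth$molecules$molecule_id))
  # different seed, different reads
  cfg2 <- sim_config(n_fragments = 30, depth = 333, cycles = 5,
                     e_pcr = 1e-4, e_seq = 0.002, seed = 62)
  expect_false(identical(simulate_library(cfg2, CODE, LAYOUT)$reads,
                         s1$reads))
})

test_that("reads are faithful renderings of their molecules at zero noise", {
  cfg <- sim_config(n_fragments = 20, depth = 100, cycles = 4, seed = 63)
  sim <- simulate_library(cfg, CODE, LAYOUT)
  mol <- sim$truth$molecules
  for (i in sample.int(100L, 10L)) {
    mid <- sim$truth$reads$molecule_id[i]
    dec <- decode_read_pair(sim$reads$seq1[i], sim$reads$seq2[i],
                            CODE, LAYOUT)
    expect_identical(dec$status, "ok")
    expect_identical(dec$key, mol$key[mol$molecule_id == mid])
  }
  expect_identical(nchar(sim$reads$seq1[1]), 151L)
})

test_that("truth error positions match the emitted sequences", {
  cfg <- sim_config(n_fragments = 10, depth = 200, cycles = 3,
                    e_seq = 0.01, seed = 65)
  sim <- simulate_library(cfg, CODE, LAYOUT)
  mol <- sim$truth$molecules
  tr <- sim$truth$reads
  lay_len <- 151L
  for (i in utils::head(which(tr$n_seq_errors > 0), 10L)) {
    mid <- tr$molecule_id[i]
    # reconstruct the clean mate-1 read and locate the mismatches
    idx <- as.integer(strsplit(mol$key[mid], "-")[[1]])
    ad1 <- list(randmer = substr(mol$randmer[mid], 1, 6),
                subunit_indices = idx[1:3])
    clean <- paste0(render_prefix(ad1, CODE, LAYOUT), mol$insert1[mid])
    obs <- sim$reads$seq1[i]
    pos <- as.integer(strsplit(tr$seq_error_positions[i], ",")[[1]])
    pos1 <- pos[pos <= lay_len]
    mism <- which(strsplit(obs, "")[[1]] != strsplit(clean, "")[[1]])
    expect_identical(mism, pos1)
  }
})

test_that("PCR-channel simulation matches the closed-form family error rate", {
  e <- 2e-4; cc <- 6L
  p <- pcr_error_prob(e, 12, cc)
  # vectorized branching oracle
  set.seed(67)
  mc <- pcr_branching_sim(e, 12, cc, n_rep = 10000L)
  expect_lt(abs(mc$p_hat - p), 3 * sqrt(p * (1 - p) / mc$n_rep))
  # the library simulator's own per-family amplification machinery: the
  # fraction of families holding any mutated copy of a 12-base template
  set.seed(68)
  n_fam <- 3000L
  any_err <- vapply(seq_len(n_fam), function(i) {
    vars <- exbtools:::.pcr_family(12L, cc, 1, e)
    any(vapply(vars, function(v) length(v$pos) > 0L, logical(1)))
  }, logical(1))
  p_obs <- mean(any_err)
  expect_lt(abs(p_obs - p), 3 * sqrt(p * (1 - p) / n_fam))
})

test_that("uniform tagging covers the label space evenly", {
  tab <- uniform_tagging_run(200000L, seed = 69)
  expect_true(all(tab$count >= 1L))
  expect_lte(nrow(tab), 262144L)
  expect_identical(sum(tab$count), 200000L)
  expect_gt(frac_within_log10(tab$count), 0.99)
  t1 <- uniform_tagging_run(1L, seed = 70)
  expect_identical(nrow(t1), 1L)
  expect_identical(frac_within_log10(t1$count), 1)
})

test_that("count evaluation separates EXB, inflated and true molecules", {
  cfg <- sim_config(n_fragments = 80, depth = 800, cycles = 5,
                    e_seq = 0.003, seed = 71)
  sim <- simulate_library(cfg, CODE, LAYOUT)
  gr <- group_reads(decode_reads(sim$reads$seq1, sim$reads$seq2, CODE,
                                 LAYOUT, sim$reads$read_id))
  rep <- evaluate_counts(gr, sim$truth)
  expect_identical(rep$true_count, 80L)
  expect_gte(rep$inflated_count, rep$exb_count)
  expect_true(rep$assignment_accuracy > 0.99)
  # zero-noise control: all three counts coincide
  cfg0 <- sim_config(n_fragments = 80, depth = 800, cycles = 5, seed = 72)
  sim0 <- simulate_library(cfg0, CODE, LAYOUT)
  gr0 <- group_reads(decode_reads(sim0$reads$seq1, sim0$reads$seq2, CODE,
                                  LAYOUT, sim0$reads$read_id))
  rep0 <- evaluate_counts(gr0, sim0$truth)
  expect_identical(rep0$exb_count, rep0$true_count)
  expect_identical(rep0$inflated_count, rep0$true_count)
  expect_identical(rep0$assignment_accuracy, 1)
})

test_that("lognormal label weights skew barcode usage", {
  cfg <- sim_config(n_fragments = 3000, depth = 3000, cycles = 0,
                    label_weights = "lognormal", label_cv = 1.5, seed = 73)
  sim <- simulate_library(cfg, CODE, LAYOUT)
  idx1 <- as.integer(substr(sim$truth$molecules$key, 1, 2))
  counts <- tabulate(idx1 + 1L, 64L)
  cv_obs <- stats::sd(counts) / mean(counts)
  cfg_u <- sim_config(n_fragments = 3000, depth = 3000, cycles = 0, seed = 73)
  sim_u <- simulate_library(cfg_u, CODE, LAYOUT)
  idx_u <- as.integer(substr(sim_u$truth$molecules$key, 1, 2))
  cv_u <- stats::sd(tabulate(idx_u + 1L, 64L)) / mean(tabulate(idx_u + 1L, 64L))
  expect_gt(cv_obs, 2 * cv_u)
})
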