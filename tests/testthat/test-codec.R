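# The barcode code: construction, encoding, syndromes, coset decoding.

test_that("default code is a 64-barcode set with minimum distance exactly 4", {
  expect_length(CODE$barcodes, 64L)
  expect_length(unique(CODE$barcodes), 64L)
  expect_identical(CODE$barcodes[1], "AAAAAA")
  d <- oracle_pair_distances()
  expect_identical(min(d), 4L)
  expect_identical(as.integer(table(d)[c("4", "6")]), c(1440L, 576L))
  # check matrix annihilates every codeword
  for (bc in CODE$barcodes)
    expect_identical(subunit_syndrome(bc, CODE), c(0L, 0L, 0L))
})

test_that("construction is deterministic and rejects low-distance matrices", {
  code2 <- build_code(exb_config())
  expect_identical(code2$barcodes, CODE$barcodes)
  # [I3 | I3] has codewords of weight 2 -> minimum distance 2
  expect_error(build_code(exb_config(generator = "CAACAAACAACAAACAAC")),
               "minimum distance")
})

test_that("encoding is systematic and injective", {
  expect_identical(encode_message("AAA", CODE), "AAAAAA")
  expect_identical(encode_message(c(0L, 0L, 0L), CODE), "AAAAAA")
  msgs <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                      b3 = c("A", "C", "G", "T"))
  words <- apply(msgs, 1L, function(m) {
    enc <- encode_message(paste(m, collapse = ""), CODE)
    expect_identical(substr(enc, 1, 3), paste(m, collapse = ""))
    enc
  })
  expect_length(unique(words), 64L)
  expect_setequal(words, CODE$barcodes)
})

test_that("syndrome is linear and localizes single substitutions", {
  # syndrome of a corrupted codeword equals v * (column j of H)
  set.seed(11)
  for (rep in 1:20) {
    cw <- sample(CODE$barcodes, 1)
    j <- sample.int(6L, 1L)
    v <- sample(1:3, 1L)
    sym <- dna_to_symbols(cw)
    sym[j] <- bitwXor(sym[j], v)
    syn <- subunit_syndrome(symbols_to_dna(sym), CODE)
    expected <- vapply(1:3, function(i) {
      m <- CODE$check[i, j]
      if (m == 0L || v == 0L) 0L
      else c(1L, 2L, 3L)[((c(0L, 1L, 2L)[m] + c(0L, 1L, 2L)[v]) %% 3L) + 1L]
    }, integer(1))
    expect_identical(syn, expected)
  }
  # additivity over word pairs under symbol-wise field addition
  set.seed(12)
  for (rep in 1:20) {
    w1 <- sample.int(4L, 6L, replace = TRUE) - 1L
    w2 <- sample.int(4L, 6L, replace = TRUE) - 1L
    s12 <- subunit_syndrome(symbols_to_dna(bitwXor(w1, w2)), CODE)
    s1 <- subunit_syndrome(symbols_to_dna(w1), CODE)
    s2 <- subunit_syndrome(symbols_to_dna(w2), CODE)
    expect_identical(s12, bitwXor(s1, s2))
  }
})

test_that("coset leaders split as 1 + 18 + 45 with minimal weights", {
  leaders <- enumerate_coset_leaders(CODE$check)
  expect_length(leaders, 64L)
  weights <- vapply(leaders, `[[`, integer(1), "weight")
  npat <- vapply(leaders, function(l) nrow(l$patterns), integer(1))
  expect_identical(sum(weights == 0L), 1L)
  expect_identical(sum(weights == 1L), 18L)
  expect_identical(sum(weights == 2L), 45L)
  expect_true(all(npat[weights <= 1L] == 1L))
  expect_true(all(npat[weights == 2L] == 3L))
  # leader weights are minimal in each coset: brute force over all 4096 words
  all_words <- expand.grid(rep(list(0:3), 6L))
  min_wt <- rep(Inf, 64L)
  for (r in seq_len(nrow(all_words))) {
    w <- as.integer(all_words[r, 6:1])
    s <- vapply(1:3, function(i) {
      acc <- 0L
      for (j in 1:6) {
        m <- CODE$check[i, j]; wj <- w[j]
        p <- if (m == 0L || wj == 0L) 0L
             else c(1L, 2L, 3L)[((c(0L, 1L, 2L)[m] + c(0L, 1L, 2L)[wj]) %% 3L) + 1L]
        acc <- bitwXor(acc, p)
      }
      acc
    }, integer(1))
    k <- 1L + s[1] * 16L + s[2] * 4L + s[3]
    min_wt[k] <- min(min_wt[k], sum(w != 0L))
  }
  expect_identical(as.integer(min_wt), weights)
})

test_that("single substitutions decode to the original codeword", {
  for (cw in CODE$barcodes) {
    truth <- oracle_nearest(cw)
    for (pos in 1:6) for (to in setdiff(c("A", "C", "G", "T"),
                                        substr(cw, pos, pos))) {
      obs <- substitute_base(cw, pos, to)
      dec <- decode_subunit(obs, CODE)
      expect_identical(dec$status, "corrected")
      expect_identical(dec$candidates, truth)
      expect_identical(dec$n_corrected_positions, 1L)
      expect_identical(oracle_nearest(obs), truth)  # oracle agrees
    }
  }
})

test_that("double substitutions are 3-way ambiguous and include the truth", {
  set.seed(21)
  sampled <- sample(CODE$barcodes, 8L)
  for (cw in sampled) {
    for (pos_pair in list(c(1, 2), c(2, 5), c(3, 6), c(5, 6))) {
      obs <- cw
      for (p in pos_pair) obs <- substitute_base(obs, p)
      dec <- decode_subunit(obs, CODE)
      expect_identical(dec$status, "ambiguous")
      expect_length(dec$candidates, 3L)
      expect_true(oracle_nearest(cw)[1] %in% dec$candidates)
      # all candidates are at equal minimal distance from the observation
      dists <- vapply(CODE$barcodes[dec$candidates + 1L], str_hamming,
                      integer(1), a = obs)
      expect_true(all(dists == 2L))
    }
  }
})

test_that("N positions are decoded as erasures", {
  cw <- CODE$barcodes[38]
  one_n <- paste0("N", substr(cw, 2, 6))
  dec <- decode_subunit(one_n, CODE)
  expect_identical(dec$status, "corrected")
  expect_identical(dec$candidates, 37L)
  # one N plus one substitution is still uniquely resolvable (d = 4)
  err <- substitute_base(one_n, 4L)
  dec2 <- decode_subunit(err, CODE)
  expect_identical(dec2$status, "corrected")
  expect_identical(dec2$candidates, 37L)
  # more than two Ns are uncorrectable
  expect_identical(decode_subunit("NNNAAA", CODE)$status, "uncorrectable")
})

test_that("the frozen generator is the lexicographic minimum of the search", {
  gens <- search_generator_matrices()
  expect_length(gens, 486L)
  expect_identical(gens[1], exb_config()$generator)
  expect_true(exb_config()$generator %in% gens)
})

test_that("barcode list and config round-trip through plain text", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_barcode_list(CODE, tmp)
  expect_identical(read_barcode_list(tmp), CODE$barcodes)
  cfgf <- withr::local_tempfile(fileext = ".cfg")
  write_exb_config(exb_config(), cfgf)
  expect_identical(read_exb_config(cfgf), exb_config())
})
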