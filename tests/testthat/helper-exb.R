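# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's syndrome machinery: decoding is checked against exhaustive
# nearest-codeword search, distances against direct string comparison.

CODE <- build_code()
LAYOUT <- build_layout()

str_hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# exhaustive nearest-codeword search: indices (0-based) of all barcodes at
# minimal substitution distance from the observed word
oracle_nearest <- function(word, barcodes = CODE$barcodes) {
  d <- vapply(barcodes, str_hamming, integer(1), a = word)
  unname(which(d == min(d)) - 1L)
}

# all pairwise substitution distances of a barcode set
oracle_pair_distances <- function(barcodes = CODE$barcodes) {
  utils::combn(length(barcodes), 2L, function(ij)
    str_hamming(barcodes[ij[1]], barcodes[ij[2]]))
}

# substitute position pos of a string with a different fixed base
substitute_base <- function(s, pos, to = NULL) {
  cur <- substr(s, pos, pos)
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), cur)[1]
  paste0(substr(s, 1L, pos - 1L), to, substr(s, pos + 1L, nchar(s)))
}

# render a full synthetic read pair for given subunit indices / randmers /
# inserts, bypassing the simulator (used for constructed fixtures)
render_read_pair <- function(idx6, randmer1, randmer2, insert1, insert2,
                             code = CODE, layout = LAYOUT) {
  ad1 <- list(randmer = randmer1, subunit_indices = idx6[1:3])
  ad2 <- list(randmer = randmer2, subunit_indices = idx6[4:6])
  list(seq1 = paste0(render_prefix(ad1, code, layout), insert1),
       seq2 = paste0(render_prefix(ad2, code, layout), insert2))
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
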