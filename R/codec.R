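# The barcode code: a [6,3,4] linear code over GF(4) ("Hexacode"-class code).
# Messages are 3 symbols, codewords 6 symbols; every pair of the 64 codewords
# differs in at least 4 positions, so any single substitution is uniquely
# correctable and any double substitution is detectable (3-way ambiguous).

# Integer index of a 6-symbol word into the 4096-entry decode table.
.word_index <- function(w) {
  1L + sum(as.integer(w) * 4L^(5:0))
}

.syndrome_key <- function(s) 1L + s[1] * 16L + s[2] * 4L + s[3]

# All 4^k symbol tuples as a (4^k x k) integer matrix, symbol order A<C<G<T,
# rows in lexicographic order of the tuple.
.all_tuples <- function(k) {
  g <- as.matrix(expand.grid(rep(list(0:3), k))[, k:1, drop = FALSE])
  colnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

.parse_generator <- function(generator) {
  sym <- dna_to_symbols(generator)
  G <- matrix(sym, nrow = 3, ncol = 6, byrow = TRUE)
  if (!all(G[, 1:3] == diag(3)))
    stop("generator matrix must be in standard form [I3 | P]")
  G
}

#' Build the 64-barcode error-correcting code
#'
#' Constructs the quaternary linear code from the configured generator
#' matrix: encodes all 64 3-symbol messages into 6-mer barcodes, derives the
#' check (decoder) matrix, enumerates the coset leaders of every syndrome,
#' and precomputes a decode table for all 4096 possible 6-mers.
#'
#' @param config An [exb_config()] object carrying the generator matrix.
#' @return An object of class `exb_code` with elements `generator` (3x6
#'   integer matrix over GF(4)), `check` (3x6), `barcodes` (character vector
#'   of 64 6-mers, indexed 0..63 by message), `leaders` (per-syndrome
#'   minimal-weight error patterns, see [enumerate_coset_leaders()]), and the
#'   originating `config`.
#' @details The check matrix is `H = [P' | I3]` (over a characteristic-2
#'   field, `-P' = P'`), so `H %*% t(G) = 0` and codewords are exactly the
#'   words with zero syndrome. Construction fails if the configured matrix
#'   yields a minimum pairwise distance below 4.
#' @examples
#' code <- build_code()
#' length(code$barcodes)   # 64
#' code$barcodes[1]        # "AAAAAA", the zero codeword
#' @export
build_code <- function(config = exb_config()) {
  G <- .parse_generator(config$generator)
  P <- G[, 4:6, drop = FALSE]
  H <- cbind(t(P), diag(3L))

  msgs <- .all_tuples(3)
  cw <- matrix(0L, 64L, 6L)
  cw[, 1:3] <- msgs
  for (j in 1:3) {
    col <- P[, j]
    acc <- integer(64)
    for (i in 1:3) acc <- gf4_add(acc, gf4_mul(msgs[, i], col[i]))
    cw[, 3L + j] <- acc
  }
  barcodes <- apply(cw, 1L, symbols_to_dna)

  # minimum distance of a linear code = minimum nonzero codeword weight
  wts <- rowSums(cw != 0L)
  dmin <- min(wts[-1L])
  if (dmin < 4L)
    stop("configured generator matrix yields minimum distance ", dmin,
         " (< 4); not a valid barcode code")

  leaders <- enumerate_coset_leaders(H)

  code <- structure(list(generator = G, check = H, barcodes = barcodes,
                         codewords = cw, min_distance = dmin,
                         leaders = leaders, config = config),
                    class = "exb_code")
  code$decode_table <- .build_decode_table(code)
  code
}

#' @export
print.exb_code <- function(x, ...) {
  cat("EXB barcode code: [6,3,", x$min_distance, "] linear code over GF(4)\n",
      sep = "")
  cat("  ", length(x$barcodes), " barcodes, generator (row-major): ",
      x$config$generator, "\n", sep = "")
  invisible(x)
}

#' Encode a 3-symbol message into its 6-mer barcode
#'
#' The generator is in standard form, so the first three bases of the
#' barcode spell the message and the last three are its linear redundancy.
#'
#' @param message Either a 3-character DNA string, or an integer vector of
#'   three GF(4) symbols (0..3).
#' @param code An `exb_code` from [build_code()].
#' @return The 6-mer barcode as a character string.
#' @examples
#' code <- build_code()
#' encode_message("AAA", code)  # "AAAAAA"
#' @export
encode_message <- function(message, code) {
  if (is.character(message)) message <- dna_to_symbols(message)
  stopifnot(length(message) == 3L, all(message %in% 0:3))
  idx <- message[1] * 16L + message[2] * 4L + message[3]
  code$barcodes[idx + 1L]
}

#' Syndrome of an observed 6-mer
#'
#' Multiplies the word into the check (decoder) matrix. Codewords map to the
#' zero vector; any nonzero result indexes the coset of error patterns
#' consistent with the observation.
#'
#' @param word A 6-character DNA string (A/C/G/T only) or integer symbol
#'   vector of length 6.
#' @param code An `exb_code`.
#' @return Integer vector of three GF(4) symbols.
#' @export
subunit_syndrome <- function(word, code) {
  if (is.character(word)) word <- dna_to_symbols(word)
  stopifnot(length(word) == 6L)
  if (anyNA(word)) stop("word contains non-ACGT symbols; see decode_subunit")
  gf4_matvec(code$check, as.integer(word))
}

#' Enumerate the coset leaders of every syndrome
#'
#' For each of the 64 syndromes, lists the minimal-weight error patterns
#' (coset leaders) consistent with it. For a distance-4 code of length 6 the
#' cosets split as: the zero syndrome (weight-0 leader), 18 syndromes with a
#' unique weight-1 leader, and 45 syndromes with exactly three weight-2
#' leaders — so the covering radius is 2 and every word decodes.
#'
#' @param check A 3x6 integer check matrix over GF(4).
#' @return A list of 64 entries keyed by syndrome (index
#'   `1 + 16*s1 + 4*s2 + s3`), each a list with `weight` and `patterns`
#'   (matrix with one 6-symbol error pattern per row).
#' @export
enumerate_coset_leaders <- function(check) {
  stopifnot(is.matrix(check), nrow(check) == 3L, ncol(check) == 6L)
  leaders <- vector("list", 64L)
  add_pattern <- function(e) {
    k <- .syndrome_key(gf4_matvec(check, e))
    w <- sum(e != 0L)
    cur <- leaders[[k]]
    if (is.null(cur)) {
      leaders[[k]] <<- list(weight = w, patterns = matrix(e, nrow = 1))
    } else if (w == cur$weight) {
      leaders[[k]]$patterns <<- rbind(cur$patterns, e)
    }                                    # heavier patterns are not leaders
  }
  add_pattern(integer(6))
  for (j in 1:6) for (v in 1:3) {        # weight 1
    e <- integer(6); e[j] <- v; add_pattern(e)
  }
  pos <- utils::combn(6, 2)
  for (k in seq_len(ncol(pos))) for (v1 in 1:3) for (v2 in 1:3) {  # weight 2
    e <- integer(6); e[pos[1, k]] <- v1; e[pos[2, k]] <- v2
    add_pattern(e)
  }
  if (any(vapply(leaders, is.null, logical(1))))
    stop("check matrix does not cover all syndromes within weight 2")
  leaders
}

# Precompute decode outcomes for every ACGT 6-mer (4096 words).
.build_decode_table <- function(code) {
  words <- .all_tuples(6)
  # syndromes for all words at once: s_i = XOR_j mul(H[i,j], w_j)
  skey <- rep(0L, 4096L)
  for (i in 1:3) {
    acc <- integer(4096)
    for (j in 1:6) acc <- gf4_add(acc, gf4_mul(code$check[i, j], words[, j]))
    skey <- skey + acc * 4L^(3L - i)
  }
  skey <- skey + 1L
  status <- character(4096)
  cands <- vector("list", 4096L)
  ncorr <- integer(4096)
  for (w in 1:4096) {
    ld <- code$leaders[[skey[w]]]
    corrected <- ld$patterns
    for (j in 1:6) corrected[, j] <- gf4_add(corrected[, j], words[w, j])
    idx <- corrected[, 1] * 16L + corrected[, 2] * 4L + corrected[, 3]
    st <- if (ld$weight == 0L) "exact"
          else if (nrow(ld$patterns) == 1L) "corrected" else "ambiguous"
    status[w] <- st
    cands[[w]] <- sort(as.integer(idx))
    ncorr[w] <- ld$weight
  }
  word_strings <- apply(words, 1L, symbols_to_dna)
  list(status = status, candidates = cands, n_corrected = ncorr,
       syndrome_key = skey,
       first_candidate = vapply(cands, `[`, integer(1), 1L),
       word_of = stats::setNames(seq_len(4096L), word_strings))
}

#' Decode one observed 6-mer subunit
#'
#' Syndrome decoding under the parsimony principle: the syndrome of the
#' observed word selects a coset, and its minimal-weight leaders are the
#' candidate error patterns. A unique weight-0 leader is an exact match, a
#' unique weight-1 leader a corrected single substitution; several
#' equal-weight leaders leave the word ambiguous (resolution is deferred to
#' the read-pool pass of [group_reads()]).
#'
#' Positions holding non-ACGT characters (N) are treated as erasures: all
#' substitutions at those positions are enumerated before syndrome decoding
#' and candidates of minimal substitution distance on the determined
#' positions are retained. More than two erasures are uncorrectable.
#'
#' @param word A 6-character string, possibly containing N.
#' @param code An `exb_code`.
#' @return A list of class `exb_decode` with `status` (one of `exact`,
#'   `corrected`, `ambiguous`, `uncorrectable`), `candidates` (integer
#'   barcode indices 0..63, lexicographically ordered), `syndrome` (3-symbol
#'   vector; `NA` for erasure-decoded words) and `n_corrected_positions`.
#' @examples
#' code <- build_code()
#' decode_subunit("AAAAAA", code)$status            # "exact"
#' decode_subunit("AAAAAT", code)$status            # "corrected"
#' @export
decode_subunit <- function(word, code) {
  stopifnot(nchar(word) == 6L)
  sym <- dna_to_symbols(word)
  nas <- which(is.na(sym))
  out <- function(status, candidates, syndrome, ncorr)
    structure(list(status = status, candidates = candidates,
                   syndrome = syndrome, n_corrected_positions = ncorr),
              class = "exb_decode")
  if (length(nas) == 0L) {
    w <- .word_index(sym)
    dt <- code$decode_table
    s <- dt$syndrome_key[w] - 1L
    syn <- as.integer(c(s %/% 16L, (s %/% 4L) %% 4L, s %% 4L))
    return(out(dt$status[w], dt$candidates[[w]], syn, dt$n_corrected[w]))
  }
  if (length(nas) > 2L)
    return(out("uncorrectable", integer(0), rep(NA_integer_, 3), NA_integer_))
  # erasure enumeration: fill N positions with every symbol combination,
  # decode each filling, keep candidates minimizing errors at non-N positions
  fills <- .all_tuples(length(nas))
  dt <- code$decode_table
  best_w <- Inf; best <- integer(0)
  for (f in seq_len(nrow(fills))) {
    sym[nas] <- fills[f, ]
    w <- .word_index(sym)
    for (cand in dt$candidates[[w]]) {
      cw <- code$codewords[cand + 1L, ]
      werr <- sum(cw[-nas] != sym[-nas])
      if (werr < best_w) { best_w <- werr; best <- cand }
      else if (werr == best_w) best <- union(best, cand)
    }
  }
  best <- sort(as.integer(best))
  status <- if (length(best) == 1L) "corrected" else "ambiguous"
  out(status, best, rep(NA_integer_, 3), as.integer(best_w))
}

#' Search all standard-form generator matrices for distance-4 codes
#'
#' Enumerates every `[I3 | P]` generator with `P` ranging over all 262,144
#' GF(4) 3x3 matrices and returns those whose 64-codeword code attains the
#' maximal minimum distance 4 (any such code is MDS with weight distribution
#' A4 = 45, A6 = 18). The default configuration freezes the
#' lexicographically smallest qualifying `P`.
#'
#' @return A character vector of qualifying generator matrices, each as 18
#'   base characters row-major, sorted lexicographically.
#' @export
search_generator_matrices <- function() {
  msgs <- .all_tuples(3)
  nz <- which(rowSums(msgs != 0L) > 0L)
  wm <- rowSums(msgs[nz, , drop = FALSE] != 0L)
  cols <- .all_tuples(3)               # candidate P columns
  D <- matrix(0L, length(nz), 64L)
  for (j in 1:64) {
    acc <- integer(length(nz))
    for (i in 1:3) acc <- gf4_add(acc, gf4_mul(msgs[nz, i], cols[j, i]))
    D[, j] <- acc
  }
  NZ <- (D != 0L) * 1L
  hits <- list()
  for (c1 in 1:64) {
    a1 <- wm + NZ[, c1]
    for (c2 in 1:64) {
      a12 <- a1 + NZ[, c2]
      ok <- which(matrixStats_colMins(a12 + NZ) >= 4L)
      for (c3 in ok) hits[[length(hits) + 1L]] <- c(c1, c2, c3)
    }
  }
  gens <- vapply(hits, function(h) {
    P <- cbind(cols[h[1], ], cols[h[2], ], cols[h[3], ])
    G <- cbind(diag(3L), P)
    symbols_to_dna(as.vector(t(G)))
  }, character(1))
  sort(gens)
}

# column minima of a plain matrix (avoids a dependency for one call)
matrixStats_colMins <- function(m) {
  do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

#' Export / import the barcode list
#'
#' Plain text, one 6-mer per line in index order (index 0 first).
#'
#' @param code An `exb_code`.
#' @param path File path.
#' @return `write_barcode_list` returns `path` invisibly;
#'   `read_barcode_list` returns the character vector of barcodes.
#' @export
write_barcode_list <- function(code, path) {
  writeLines(code$barcodes, path)
  invisible(path)
}

#' @rdname write_barcode_list
#' @export
read_barcode_list <- function(path) {
  bc <- readLines(path)
  bc <- bc[nzchar(bc)]
  if (length(bc) != 64L || any(nchar(bc) != 6L))
    stop("expected 64 6-mers, one per line")
  bc
}
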