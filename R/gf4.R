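# Arithmetic over GF(4) = {0, 1, w, w^2}, encoded as integers 0:3 with the
# base mapping A=0, C=1, G=w (2), T=w^2 (3). Addition is characteristic-2
# (bitwise XOR on the 2-bit labels); multiplication uses the cyclic group of
# the three nonzero elements (w^3 = 1).

.gf4_mul_table <- local({
  m <- matrix(0L, 4L, 4L)
  pow <- c(1L, 2L, 3L)               # w^0, w^1, w^2 as labels
  lg <- c(0L, 1L, 2L)                # discrete logs of 1, 2, 3
  for (a in 1:3) for (b in 1:3)
    m[a + 1L, b + 1L] <- pow[(lg[a] + lg[b]) %% 3L + 1L]
  m
})

gf4_add <- function(a, b) bitwXor(as.integer(a), as.integer(b))

gf4_mul <- function(a, b) .gf4_mul_table[cbind(as.integer(a) + 1L, as.integer(b) + 1L)]

# Symbol-wise GF(4) dot product of two equal-length vectors.
gf4_dot <- function(x, y) {
  acc <- 0L
  for (p in gf4_mul(x, y)) acc <- gf4_add(acc, p)
  acc
}

# Matrix-vector product H %*% w over GF(4); H integer matrix, w integer vector.
gf4_matvec <- function(H, w) {
  vapply(seq_len(nrow(H)), function(i) gf4_dot(H[i, ], w), integer(1))
}

.DNA_BASES <- c("A", "C", "G", "T")

#' Convert DNA characters to GF(4) symbols
#'
#' Maps A, C, G, T to the field labels 0, 1, 2, 3 (A is the zero element).
#' Characters outside the alphabet (such as N) map to `NA`.
#'
#' @param x A character string of DNA bases, or a character vector of
#'   single bases.
#' @return An integer vector of symbols in 0..3, `NA` for non-ACGT input.
#' @export
dna_to_symbols <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  match(x, .DNA_BASES) - 1L
}

#' Convert GF(4) symbols to DNA characters
#'
#' @param s Integer vector of symbols in 0..3.
#' @param collapse If `TRUE` (default) return one string, else a character
#'   vector of single bases.
#' @return DNA bases under the A=0, C=1, G=2, T=3 mapping.
#' @export
symbols_to_dna <- function(s, collapse = TRUE) {
  b <- .DNA_BASES[as.integer(s) + 1L]
  if (collapse) paste(b, collapse = "") else b
}

# Reverse complement of a plain character DNA string.
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Hamming (substitution) distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}
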