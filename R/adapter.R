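# Adapter geometry and the combinatorial oligonucleotide set. Each read of a
# pair starts with an inline prefix: 6 bp random-mer, three 6 bp barcode
# subunits separated by scaffolds, then the 19 bp transposase recognition
# sequence, followed by the cDNA insert.

# Standard Illumina read-2 primer site; the second common oligo is synthesized
# as its reverse complement. A synthetic convention (the wet-lab oligo list
# is assay-specific), fixed here for reproducibility.
.READ2_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

#' Build the adapter layout
#'
#' Computes the segment offsets of the inline EXB prefix from a
#' configuration. With the default 6-base random-mer, 6-base subunits,
#' 10/9/9-base scaffolds and the 19-base recognition sequence the prefix is
#' 71 bases, leaving 80 insert bases of a 151-base read.
#'
#' @param config An [exb_config()] object.
#' @return An object of class `exb_layout`: segment lengths, a named list
#'   `offsets` of `c(start, end)` (1-based, inclusive) for segments
#'   `randmer`, `subunit1`, `scaffold_a`, `subunit2`, `scaffold_b`,
#'   `subunit3`, `scaffold_c`, `me`, plus `prefix_len`, `read_len` and
#'   `insert_capacity = read_len - prefix_len`.
#' @examples
#' lay <- build_layout()
#' lay$prefix_len        # 71
#' lay$insert_capacity   # 80
#' @export
build_layout <- function(config = exb_config()) {
  sl <- nchar(config$scaffolds)
  if (any(sl < 0)) stop("scaffold lengths must be nonnegative")
  lens <- c(randmer = config$randmer_len,
            subunit1 = 6L, scaffold_a = sl[1],
            subunit2 = 6L, scaffold_b = sl[2],
            subunit3 = 6L, scaffold_c = sl[3],
            me = nchar(config$me_seq))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  offsets <- Map(function(s, e) c(start = s, end = e), starts, ends)
  prefix_len <- unname(ends[length(ends)])
  structure(list(randmer_len = config$randmer_len, subunit_len = 6L,
                 scaffolds = config$scaffolds, me_seq = config$me_seq,
                 offsets = offsets, prefix_len = prefix_len,
                 read_len = config$read_len,
                 insert_capacity = config$read_len - prefix_len,
                 config = config),
            class = "exb_layout")
}

#' @export
print.exb_layout <- function(x, ...) {
  cat("EXB adapter layout: prefix", x$prefix_len, "bp,",
      x$insert_capacity, "insert bp at read length", x$read_len, "\n")
  invisible(x)
}

#' Single-end and paired-end label-space sizes
#'
#' Three subunits of 64 barcodes give `64^3 = 262,144` labels per read end;
#' both ends jointly give `262,144^2 = 68,719,476,736` paired-end labels.
#'
#' @param code An `exb_code`.
#' @return A named numeric vector with `single_end` and `paired_end`
#'   (numeric because the paired-end count exceeds 32-bit integer range).
#' @export
label_space <- function(code = NULL) {
  k <- if (is.null(code)) 64 else length(code$barcodes)
  single <- k^3
  c(single_end = single, paired_end = single^2)
}

#' Enumerate the combinatorial oligonucleotide set
#'
#' The assembly scheme needs one oligo per barcode per subunit slot plus two
#' common oligos: `3 * 64 + 2 = 194` sequences (192 barcode-bearing). Group-1
#' oligos carry the random-mer region (rendered as Ns) followed by the
#' barcode and scaffold A; group-2 and group-3 oligos carry their barcode
#' followed by scaffolds B and C. The common oligos are the reverse
#' complements of the transposase recognition sequence and of the read-2
#' sequencing adapter. Concatenating one oligo per group with the recognition
#' sequence reconstructs the full inline prefix.
#'
#' @param code An `exb_code`.
#' @param layout An `exb_layout`.
#' @return A data.frame with columns `name`, `group` (`subunit1/2/3` or
#'   `common`) and `sequence`.
#' @examples
#' oligos <- enumerate_oligos(build_code(), build_layout())
#' nrow(oligos)                          # 194
#' sum(oligos$group != "common")         # 192
#' @export
enumerate_oligos <- function(code, layout) {
  bc <- code$barcodes
  k <- length(bc)
  nmer <- strrep("N", layout$randmer_len)
  df <- rbind(
    data.frame(name = sprintf("sub1_bc%02d", seq_len(k) - 1L),
               group = "subunit1",
               sequence = paste0(nmer, bc, layout$scaffolds[1])),
    data.frame(name = sprintf("sub2_bc%02d", seq_len(k) - 1L),
               group = "subunit2",
               sequence = paste0(bc, layout$scaffolds[2])),
    data.frame(name = sprintf("sub3_bc%02d", seq_len(k) - 1L),
               group = "subunit3",
               sequence = paste0(bc, layout$scaffolds[3])),
    data.frame(name = c("common_me_rc", "common_read2_rc"),
               group = "common",
               sequence = c(revcomp(layout$me_seq), revcomp(.READ2_ADAPTER)))
  )
  rownames(df) <- NULL
  df
}

#' Write the oligo set as tab-separated text
#'
#' @param oligos A data.frame from [enumerate_oligos()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oligo_set <- function(oligos, path) {
  utils::write.table(oligos, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sample a random EXB adapter
#'
#' Draws one barcode index per subunit slot (independently, uniformly or
#' under per-slot weights) and a uniform random-mer. Uses R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param code An `exb_code`.
#' @param layout An `exb_layout`.
#' @param weights `NULL` for uniform sampling, or a list of three numeric
#'   vectors of length 64 (nonnegative, not all zero) weighting each slot.
#' @return A list of class `exb_adapter` with `randmer` (character) and
#'   `subunit_indices` (integer vector of 3, values 0..63).
#' @export
sample_adapter <- function(code, layout, weights = NULL) {
  k <- length(code$barcodes)
  if (is.null(weights)) weights <- rep(list(rep(1, k)), 3L)
  stopifnot(length(weights) == 3L)
  idx <- vapply(weights, function(w) {
    stopifnot(length(w) == k, all(w >= 0))
    if (sum(w) == 0) stop("all-zero subunit weights")
    sample.int(k, 1L, prob = w) - 1L
  }, integer(1))
  randmer <- paste(sample(.DNA_BASES, layout$randmer_len, replace = TRUE),
                   collapse = "")
  structure(list(randmer = randmer, subunit_indices = idx),
            class = "exb_adapter")
}

#' Render the inline prefix of an adapter
#'
#' Concatenates random-mer, barcode subunits, scaffolds and the recognition
#' sequence in layout order.
#'
#' @param adapter An `exb_adapter` (or any list with `randmer` and
#'   `subunit_indices`).
#' @param code An `exb_code`.
#' @param layout An `exb_layout`.
#' @return The prefix as a character string of length `layout$prefix_len`.
#' @export
render_prefix <- function(adapter, code, layout) {
  b <- code$barcodes[adapter$subunit_indices + 1L]
  paste0(adapter$randmer, b[1], layout$scaffolds[1], b[2],
         layout$scaffolds[2], b[3], layout$scaffolds[3], layout$me_seq)
}
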