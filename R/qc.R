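# Quality-control profiles over decoded reads: per-position mismatch along
# the inline prefix, GC content of the barcode bases, and single-end label
# abundance statistics.

#' QC profiles of decoded reads
#'
#' Uses unambiguously decoded reads. The expected prefix of each read end is
#' re-rendered from its decoded barcode indices (with the observed
#' random-mer, which has no expected sequence); the mismatch profile is the
#' per-position fraction of reads whose observed base differs, pooled over
#' both ends. Random-mer positions are reported as `NA` and excluded from
#' the mean. GC is computed over the 18 decoded barcode bases of each
#' observed read end. Abundance statistics summarize the per-single-end
#' label counts.
#'
#' @param decoded An `exb_decoded` table from [decode_reads()].
#' @param code An `exb_code`.
#' @param layout An `exb_layout`.
#' @return A list of class `exb_qc`: `mismatch_profile` (data.table
#'   `position`, `segment`, `rate`), `mean_mismatch_rate` (over non-randmer
#'   positions), `gc_histogram` (data.table `gc`, `count`; counts sum to the
#'   number of observed read ends), and `abundance` (list with `n_labels`,
#'   `cv`, `frac_within_log10` of the median count).
#' @export
qc_profiles <- function(decoded, code, layout) {
  ok <- decoded[decoded$status == "ok", ]
  if (nrow(ok) == 0L) stop("no unambiguously decoded reads")
  pl <- layout$prefix_len

  render_expected <- function(randmer, i1, i2, i3) {
    b <- code$barcodes
    paste0(randmer, b[i1 + 1L], layout$scaffolds[1], b[i2 + 1L],
           layout$scaffolds[2], b[i3 + 1L], layout$scaffolds[3],
           layout$me_seq)
  }
  r1 <- substr(ok$randmer, 1L, layout$randmer_len)
  r2 <- substr(ok$randmer, layout$randmer_len + 1L, 2L * layout$randmer_len)
  exp1 <- render_expected(r1, ok$b1, ok$b2, ok$b3)
  exp2 <- render_expected(r2, ok$b4, ok$b5, ok$b6)

  char_mat <- function(x) {
    matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
           nrow = length(x), byrow = TRUE)
  }
  mism <- (char_mat(ok$prefix1) != char_mat(exp1)) +
          (char_mat(ok$prefix2) != char_mat(exp2))
  rate <- colSums(mism) / (2L * nrow(ok))

  segment <- character(pl)
  for (nm in names(layout$offsets)) {
    o <- layout$offsets[[nm]]
    if (o["end"] >= o["start"]) segment[o["start"]:o["end"]] <- nm
  }
  rate[segment == "randmer"] <- NA_real_
  profile <- data.table::data.table(position = seq_len(pl),
                                    segment = segment, rate = rate)

  gc_bc <- vapply(strsplit(code$barcodes, "", fixed = TRUE),
                  function(ch) sum(ch %in% c("G", "C")), integer(1))
  gc_ends <- c(gc_bc[ok$b1 + 1L] + gc_bc[ok$b2 + 1L] + gc_bc[ok$b3 + 1L],
               gc_bc[ok$b4 + 1L] + gc_bc[ok$b5 + 1L] + gc_bc[ok$b6 + 1L])
  gc_histogram <- data.table::data.table(
    gc = 0:18, count = tabulate(gc_ends + 1L, nbins = 19L))

  labels <- c(paste(sprintf("%02d", ok$b1), sprintf("%02d", ok$b2),
                    sprintf("%02d", ok$b3), sep = "-"),
              paste(sprintf("%02d", ok$b4), sprintf("%02d", ok$b5),
                    sprintf("%02d", ok$b6), sep = "-"))
  counts <- table(labels)
  med <- stats::median(counts)
  abundance <- list(
    n_labels = length(counts),
    cv = stats::sd(counts) / mean(counts),
    frac_within_log10 = mean(counts >= med / 10 & counts <= med * 10))

  structure(list(mismatch_profile = profile,
                 mean_mismatch_rate = mean(rate, na.rm = TRUE),
                 gc_histogram = gc_histogram, abundance = abundance),
            class = "exb_qc")
}

#' Theoretical GC distribution of all single-end labels
#'
#' The GC count of a single-end label (18 barcode bases) is the sum of the
#' GC counts of its three subunits, so the distribution over all 262,144
#' labels is the threefold convolution of the 64-barcode GC distribution.
#'
#' @param code An `exb_code`.
#' @return A data.table with `gc` (0..18) and `n_labels` summing to `64^3`.
#' @export
theoretical_gc_distribution <- function(code) {
  gc_bc <- vapply(strsplit(code$barcodes, "", fixed = TRUE),
                  function(ch) sum(ch %in% c("G", "C")), integer(1))
  v1 <- tabulate(gc_bc + 1L, nbins = 7L)          # counts over gc 0..6
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) if (a[i] > 0)
      out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
    out
  }
  v3 <- conv(conv(v1, v1), v1)
  data.table::data.table(gc = 0:18, n_labels = v3)
}

#' Write a QC profile table
#'
#' @param qc An `exb_qc` object.
#' @param path Output TSV path for the mismatch profile.
#' @return `path`, invisibly.
#' @export
write_qc_profile <- function(qc, path) {
  utils::write.table(qc$mismatch_profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
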