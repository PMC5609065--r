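# Consensus calling over read groups and removal of 3' adapter read-through.

# Plurality base per position over covering members; ties (or no covering
# ACGT base) yield N. Consensus length is the lower-median member length,
# which resists overextension by chimeric or truncated members.
consensus_seq <- function(seqs) {
  n <- length(seqs)
  if (n == 1L) return(seqs)
  lens <- nchar(seqs)
  L <- sort(lens)[ceiling(n / 2)]
  if (L == 0L) return("")
  m <- matrix(NA_character_, n, L)
  for (i in seq_len(n)) {
    ci <- strsplit(substr(seqs[i], 1L, L), "", fixed = TRUE)[[1]]
    if (length(ci)) m[i, seq_along(ci)] <- ci
  }
  counts <- vapply(.DNA_BASES, function(b) colSums(m == b, na.rm = TRUE),
                   numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L)
  mx <- apply(counts, 1L, max)
  top <- max.col(counts, ties.method = "first")
  tie <- rowSums(counts == mx) > 1L
  out <- .DNA_BASES[top]
  out[tie | mx == 0] <- "N"
  paste(out, collapse = "")
}

#' Build consensus reads for every group
#'
#' For each read group and each mate, calls the per-position plurality base
#' over the members' insert sequences; positions where a plurality cannot be
#' distinguished (equal top counts) are emitted as N. Only the insert (the
#' bases after the inline prefix) is collapsed — the prefix content is
#' already captured by the group key.
#'
#' @param groups An `exb_groups` object from [group_reads()].
#' @return A data.table of class `exb_consensus` with columns `key`, `size`,
#'   `seq1`, `seq2`.
#' @examples
#' consensus_seq_members <- c("ACGT", "ACGA", "ACGT")  # -> "ACGT"
#' @export
build_consensus <- function(groups) {
  g <- groups$groups
  out <- .dt_keyed(
    g$key, size = g$size,
    seq1 = vapply(g$inserts1, consensus_seq, character(1)),
    seq2 = vapply(g$inserts2, consensus_seq, character(1)))
  data.table::setattr(out, "class", c("exb_consensus", class(out)))
  out
}

#' Trim 3' adapter read-through from consensus sequences
#'
#' Locates the transposase-recognition read-through sequence
#' (`CTGTCTCTTATACACATCT` by default) anywhere in each consensus mate,
#' allowing substitutions and indels up to `max_error_rate` of the target
#' length, and removes everything from the leftmost hit to the 3' end.
#' Pairs where either mate falls below `min_length` after trimming are
#' dropped.
#'
#' @param consensus An `exb_consensus` table.
#' @param max_error_rate Maximum error fraction of the target length
#'   (default 0.1, the conventional trimmer default); must lie in
#'   \[0, 0.3\].
#' @param min_length Minimum post-trim sequence length to keep a pair
#'   (default 20).
#' @param trim_seq The read-through target sequence.
#' @return A list with `consensus` (the kept, trimmed `exb_consensus`) and
#'   `dropped` (data.table of `key` and `reason` for removed pairs).
#' @export
trim_readthrough <- function(consensus, max_error_rate = 0.1,
                             min_length = 20L,
                             trim_seq = "CTGTCTCTTATACACATCT") {
  stopifnot(max_error_rate >= 0, max_error_rate <= 0.3)
  max_err <- floor(max_error_rate * nchar(trim_seq))
  trim_one <- function(s) {
    if (is.na(s) || nchar(s) < nchar(trim_seq) - max_err) return(s)
    hits <- Biostrings::matchPattern(trim_seq, Biostrings::DNAString(s),
                                     max.mismatch = max_err,
                                     with.indels = TRUE, fixed = FALSE)
    if (length(hits) == 0L) return(s)
    substr(s, 1L, min(Biostrings::start(hits)) - 1L)
  }
  t1 <- vapply(consensus$seq1, trim_one, character(1), USE.NAMES = FALSE)
  t2 <- vapply(consensus$seq2, trim_one, character(1), USE.NAMES = FALSE)
  short <- nchar(t1) < min_length | nchar(t2) < min_length
  kept <- .dt_keyed(consensus$key[!short], size = consensus$size[!short],
                    seq1 = t1[!short], seq2 = t2[!short])
  data.table::setattr(kept, "class", c("exb_consensus", class(kept)))
  dropped <- .dt_keyed(consensus$key[short],
                       reason = rep("short_after_trim", sum(short)))
  list(consensus = kept, dropped = dropped)
}

#' Write consensus reads as interleaved paired-end FASTA
#'
#' Mate records are adjacent with `/1` and `/2` name suffixes; no quality
#' lines (consensus bases have no meaningful qualities).
#'
#' @param consensus An `exb_consensus` table.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_interleaved_fasta <- function(consensus, path) {
  n <- nrow(consensus)
  seqs <- character(2L * n)
  nms <- character(2L * n)
  if (n > 0L) {
    seqs[seq(1L, 2L * n, 2L)] <- consensus$seq1
    seqs[seq(2L, 2L * n, 2L)] <- consensus$seq2
    nms[seq(1L, 2L * n, 2L)] <- paste0(consensus$key, "/1")
    nms[seq(2L, 2L * n, 2L)] <- paste0(consensus$key, "/2")
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nms
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
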