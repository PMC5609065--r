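# Decoding paired reads into EXB read groups. Each mate carries the inline
# prefix; the six decoded subunit indices (three per mate) form the grouping
# key. Reads whose subunits decode exactly or with a single corrected
# substitution are grouped directly; ambiguous reads are resolved against
# the pool of keys observed among unambiguous reads, mirroring the
# low-overlap assumption of the barcode space.

.key_of <- function(idx) paste(sprintf("%02d", idx), collapse = "-")

# data.table with a column named "key" ("key" clashes with the constructor's
# own argument, so it is set after construction)
.dt_keyed <- function(key_values, ...) {
  dt <- data.table::data.table(...)
  data.table::set(dt, j = "key", value = key_values)
  data.table::setcolorder(dt, c("key", setdiff(names(dt), "key")))
  dt
}

#' Read paired FASTQ files
#'
#' Thin wrapper over Biostrings FASTQ input; plain or gzip compressed, two
#' files or one interleaved file. Qualities are carried but unused by the
#' consensus caller.
#'
#' @param fastq1 Path to the R1 FASTQ (or the interleaved file).
#' @param fastq2 Path to the R2 FASTQ, or `NULL` with `interleaved = TRUE`.
#' @param interleaved If `TRUE`, `fastq1` holds alternating mates.
#' @return A data.table with columns `read_id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2 = NULL, interleaved = FALSE) {
  rd <- function(p) {
    # Biostrings warns that FASTQ metadata columns are dropped; irrelevant here
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          tryInvokeRestart("muffleWarning")
      })
    list(id = names(x), seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
  }
  if (interleaved) {
    a <- rd(fastq1)
    n <- length(a$seq)
    if (n %% 2L != 0L) stop("interleaved FASTQ has an odd number of records")
    odd <- seq(1L, n, 2L); even <- seq(2L, n, 2L)
    dt <- data.table::data.table(
      read_id = sub("/1$", "", a$id[odd]),
      seq1 = unname(a$seq[odd]), seq2 = unname(a$seq[even]),
      qual1 = unname(a$qual[odd]), qual2 = unname(a$qual[even]))
  } else {
    a <- rd(fastq1); b <- rd(fastq2)
    if (length(a$seq) != length(b$seq)) stop("mate files differ in length")
    dt <- data.table::data.table(
      read_id = sub("/1$", "", a$id),
      seq1 = unname(a$seq), seq2 = unname(b$seq),
      qual1 = unname(a$qual), qual2 = unname(b$qual))
  }
  dt
}

#' Extract prefix segments from one read pair
#'
#' Cuts each mate at the fixed layout offsets into random-mer, the three
#' barcode subunits, and the insert (all bases after the prefix).
#'
#' @param seq1,seq2 Mate sequences (character strings).
#' @param layout An `exb_layout`.
#' @return A list with elements `end1` and `end2`, each holding `randmer`,
#'   `subunits` (character vector of 3) and `insert`; or an error if either
#'   mate is shorter than the prefix.
#' @export
extract_segments <- function(seq1, seq2, layout) {
  if (nchar(seq1) < layout$prefix_len || nchar(seq2) < layout$prefix_len)
    stop("read shorter than the ", layout$prefix_len, "-base prefix")
  one <- function(s) {
    off <- layout$offsets
    seg <- function(nm) substr(s, off[[nm]]["start"], off[[nm]]["end"])
    list(randmer = seg("randmer"),
         subunits = c(seg("subunit1"), seg("subunit2"), seg("subunit3")),
         insert = substr(s, layout$prefix_len + 1L, nchar(s)))
  }
  list(end1 = one(seq1), end2 = one(seq2))
}

# Vectorized per-column subunit decode. Returns list(category, index, cand):
# category 0 = unambiguous (exact/corrected), 1 = ambiguous, 2 = uncorrectable.
.decode_column <- function(words, code) {
  dt <- code$decode_table
  n <- length(words)
  category <- integer(n); index <- rep(NA_integer_, n)
  cand <- vector("list", n)
  widx <- dt$word_of[words]
  pure <- !is.na(widx)
  st <- dt$status[widx[pure]]
  amb <- st == "ambiguous"
  category[pure][amb] <- 1L
  index[pure] <- ifelse(amb, NA_integer_, dt$first_candidate[widx[pure]])
  if (any(amb)) cand[which(pure)[amb]] <- dt$candidates[widx[pure][amb]]
  for (i in which(!pure)) {
    d <- decode_subunit(words[i], code)
    if (d$status == "uncorrectable") category[i] <- 2L
    else if (length(d$candidates) == 1L) index[i] <- d$candidates
    else { category[i] <- 1L; cand[[i]] <- d$candidates }
  }
  list(category = category, index = index, cand = cand)
}

#' Decode a stream of read pairs into EXB keys
#'
#' Extracts the six subunits of every pair and syndrome-decodes them. A pair
#' is `ok` when all six subunits decode exactly or with a single corrected
#' substitution (its key is the 6-index tuple), `ambiguous` when at least one
#' subunit has several equal-parsimony candidates (the candidate keys are the
#' Cartesian product of per-subunit candidates), and discarded when any
#' subunit is uncorrectable or a mate is shorter than the prefix.
#'
#' @param seq1,seq2 Character vectors of mate sequences.
#' @param code An `exb_code`.
#' @param layout An `exb_layout`.
#' @param ids Optional read identifiers (default `read1..readN`).
#' @return A data.table of class `exb_decoded` with columns `read_id`,
#'   `status` (`ok`/`ambiguous`/`discard`), `reason`, `key`, `cand_keys`
#'   (list column of candidate keys for ambiguous reads), `randmer`
#'   (combined 12-base random-mer), `insert1`, `insert2`, `prefix1`,
#'   `prefix2`, and the six decoded indices `b1..b6` where unambiguous.
#' @export
decode_reads <- function(seq1, seq2, code, layout, ids = NULL) {
  n <- length(seq1)
  stopifnot(length(seq2) == n)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  pl <- layout$prefix_len
  long_enough <- nchar(seq1) >= pl & nchar(seq2) >= pl

  off <- layout$offsets
  seg <- function(s, nm) substr(s, off[[nm]]["start"], off[[nm]]["end"])
  sub_cols <- vector("list", 6L)
  snames <- c("subunit1", "subunit2", "subunit3")
  for (j in 1:3) sub_cols[[j]] <- seg(seq1, snames[j])
  for (j in 1:3) sub_cols[[3L + j]] <- seg(seq2, snames[j])

  dec <- lapply(sub_cols, function(w) {
    w[!long_enough] <- "AAAAAA"          # placeholder, discarded below
    .decode_column(w, code)
  })
  catm <- do.call(cbind, lapply(dec, `[[`, "category"))
  idxm <- do.call(cbind, lapply(dec, `[[`, "index"))

  status <- rep("ok", n); reason <- rep(NA_character_, n)
  any_unc <- rowSums(catm == 2L) > 0L
  any_amb <- rowSums(catm == 1L) > 0L
  status[any_amb] <- "ambiguous"
  status[any_unc] <- "discard"; reason[any_unc] <- "uncorrectable_subunit"
  status[!long_enough] <- "discard"; reason[!long_enough] <- "read_too_short"

  key <- rep(NA_character_, n)
  ok <- status == "ok"
  if (any(ok)) {
    km <- matrix(sprintf("%02d", idxm[ok, , drop = FALSE]), ncol = 6L)
    key[ok] <- do.call(paste, c(as.data.frame(km, stringsAsFactors = FALSE),
                                sep = "-"))
  }
  cand_keys <- vector("list", n)
  for (i in which(status == "ambiguous")) {
    lists <- lapply(1:6, function(j)
      if (catm[i, j] == 1L) dec[[j]]$cand[[i]] else idxm[i, j])
    grid <- as.matrix(expand.grid(lists))
    cand_keys[[i]] <- sort(apply(grid, 1L, .key_of))
  }

  out <- .dt_keyed(
    key,
    read_id = ids, status = status, reason = reason,
    cand_keys = cand_keys,
    randmer = paste0(seg(seq1, "randmer"), seg(seq2, "randmer")),
    insert1 = substr(seq1, pl + 1L, nchar(seq1)),
    insert2 = substr(seq2, pl + 1L, nchar(seq2)),
    prefix1 = substr(seq1, 1L, pl), prefix2 = substr(seq2, 1L, pl))
  for (j in 1:6) data.table::set(out, j = paste0("b", j), value = idxm[, j])
  if (any(!long_enough))
    data.table::set(out, i = which(!long_enough),
                    j = c("randmer", "insert1", "insert2", "prefix1", "prefix2"),
                    value = NA_character_)
  data.table::setattr(out, "class", c("exb_decoded", class(out)))
  out
}

#' Decode one read pair
#'
#' Single-pair convenience over [decode_reads()]: returns the candidate keys
#' and status for one extracted pair.
#'
#' @param seq1,seq2 Mate sequences.
#' @param code An `exb_code`.
#' @param layout An `exb_layout`.
#' @return A list with `status`, `key` (when unambiguous), and `cand_keys`.
#' @export
decode_read_pair <- function(seq1, seq2, code, layout) {
  d <- decode_reads(seq1, seq2, code, layout)
  list(status = d$status[1], key = d$key[1], cand_keys = d$cand_keys[[1]])
}

#' Group decoded reads by EXB key
#'
#' Two-pass grouping. Pass 1 groups all unambiguous reads and records the
#' pool of observed keys. Pass 2 resolves each ambiguous read against that
#' pool: exactly one candidate present in the pool assigns the read there;
#' no candidate present makes the read a unique molecule under its
#' lexicographically smallest candidate key; several pool matches discard
#' the read (misassignment would corrupt molecule counts).
#'
#' @param decoded An `exb_decoded` table from [decode_reads()].
#' @return An object of class `exb_groups`: list with `groups` (data.table
#'   `key`, `size`, `n_distinct_randmers`, plus list columns `read_ids`,
#'   `randmers`, `inserts1`, `inserts2`), `assignments` (`read_id`, `key`,
#'   `how`), `discards` (`read_id`, `reason`) and `n_input`. Grouping is
#'   insertion-order invariant: any permutation of the input yields the same
#'   groups.
#' @export
group_reads <- function(decoded) {
  asg_key <- decoded$key
  how <- ifelse(decoded$status == "ok", "unambiguous", NA_character_)
  disc_reason <- decoded$reason

  pool <- unique(decoded$key[decoded$status == "ok"])
  for (i in which(decoded$status == "ambiguous")) {
    cand <- decoded$cand_keys[[i]]
    hit <- cand[cand %in% pool]
    if (length(hit) == 1L) {
      asg_key[i] <- hit; how[i] <- "pool_resolved"
    } else if (length(hit) == 0L) {
      asg_key[i] <- cand[1L]             # keys sort as index tuples
      how[i] <- "novel_canonical"
    } else {
      disc_reason[i] <- "ambiguous_multi_pool"
    }
  }

  assigned <- !is.na(asg_key)
  assignments <- .dt_keyed(asg_key[assigned],
                           read_id = decoded$read_id[assigned],
                           how = how[assigned])
  discards <- data.table::data.table(
    read_id = decoded$read_id[!assigned],
    reason = disc_reason[!assigned])

  dt <- .dt_keyed(
    asg_key[assigned], read_id = decoded$read_id[assigned],
    randmer = decoded$randmer[assigned],
    insert1 = decoded$insert1[assigned], insert2 = decoded$insert2[assigned])
  groups <- dt[, list(size = .N,
                      n_distinct_randmers = data.table::uniqueN(randmer),
                      read_ids = list(read_id), randmers = list(randmer),
                      inserts1 = list(insert1), inserts2 = list(insert2)),
               by = "key"]
  data.table::setorder(groups, key)
  structure(list(groups = groups, assignments = assignments,
                 discards = discards, n_input = nrow(decoded)),
            class = "exb_groups")
}

#' @export
print.exb_groups <- function(x, ...) {
  cat("EXB read groups:", nrow(x$groups), "groups from", x$n_input,
      "read pairs (", nrow(x$discards), "discarded )\n")
  invisible(x)
}

#' Write the per-group summary table
#'
#' @param groups An `exb_groups` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(groups, path) {
  g <- groups$groups[, c("key", "size", "n_distinct_randmers")]
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
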