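# Synthetic EXB-tagged library generator with ground truth. Emulates
# single-molecule tagging (one independent adapter per read end), branching
# PCR amplification with heritable per-base substitution errors, read
# sampling proportional to final copy numbers, and per-base sequencing
# errors. All randomness flows from one master seed through labeled
# per-phase substreams so each phase is individually reproducible.

#' Simulation configuration
#'
#' @param n_fragments Number of tagged cDNA molecules (>= 1).
#' @param depth Total read pairs to emit (sampled with replacement).
#' @param insert_source `"random"` for i.i.d. uniform bases, or a FASTA path
#'   whose sequences are sampled (windows of `insert_len`).
#' @param insert_len Insert length in bases (default 80, the insert capacity
#'   of a 151-base read under the default layout).
#' @param cycles PCR cycles (default 10).
#' @param pcr_efficiency Per-cycle duplication probability in (0, 1\]
#'   (default 1, so final copy number is `2^cycles`).
#' @param e_pcr Per-base substitution rate per synthesis during PCR.
#' @param e_seq Per-base substitution rate during sequencing.
#' @param read_len Read length in bases (default 151).
#' @param label_weights `"uniform"` or `"lognormal"` per-slot barcode usage.
#' @param label_cv Target coefficient of variation of barcode usage when
#'   `label_weights = "lognormal"`.
#' @param seed Master seed; fully determines the output.
#' @return An object of class `exb_sim_config`.
#' @export
sim_config <- function(n_fragments, depth, insert_source = "random",
                       insert_len = 80L, cycles = 10L, pcr_efficiency = 1,
                       e_pcr = 0, e_seq = 0, read_len = 151L,
                       label_weights = c("uniform", "lognormal"),
                       label_cv = 0.75, seed = 1L) {
  label_weights <- match.arg(label_weights)
  stopifnot(n_fragments >= 1, depth >= 1, insert_len >= 1, cycles >= 0,
            pcr_efficiency > 0, pcr_efficiency <= 1,
            e_pcr >= 0, e_pcr < 1, e_seq >= 0, e_seq < 1, read_len >= 1)
  structure(as.list(environment()), class = "exb_sim_config")
}

# substream seeds derived from the master seed (kept below 2^31)
.phase_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 5L),
                  c("tagging", "inserts", "pcr", "sampling", "seqerr"))
}

.random_dna <- function(n, len) {
  m <- matrix(sample(.DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# mutate string s at 1-based positions to random different bases
.mutate_at <- function(s, pos) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) {
    cur <- ch[p]
    alt <- .DNA_BASES[.DNA_BASES != cur]
    ch[p] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

# number of errors per mutated copy: Binomial(L, e) conditioned on >= 1
.rcond_binom <- function(n, L, e) {
  p0 <- stats::pbinom(0, L, e)
  stats::qbinom(stats::runif(n, p0, 1), L, e)
}

# Branching PCR of one template: returns data.frame(mut, count) where mut is
# a list-column of cumulative mutated positions (with bases). Every copy
# taking part in a duplication carries a newly synthesized strand, so both
# products receive fresh i.i.d. error chances each cycle (heritable).
.pcr_family <- function(len, cycles, efficiency, e) {
  p_any <- 1 - (1 - e)^len
  vars <- list(list(pos = integer(0), count = 1))
  for (cyc in seq_len(cycles)) {
    nxt <- list()
    for (v in vars) {
      k <- v$count
      dup <- if (efficiency >= 1) k else stats::rbinom(1L, k, efficiency)
      untouched <- k - dup
      exposed <- 2L * dup
      n_mut <- if (e > 0 && exposed > 0) stats::rbinom(1L, exposed, p_any)
               else 0L
      clean <- untouched + exposed - n_mut
      if (clean > 0) nxt[[length(nxt) + 1L]] <- list(pos = v$pos, count = clean)
      if (n_mut > 0) {
        n_err <- .rcond_binom(n_mut, len, e)
        for (i in seq_len(n_mut)) {
          newpos <- sample.int(len, n_err[i])
          nxt[[length(nxt) + 1L]] <-
            list(pos = c(v$pos, newpos), count = 1)
        }
      }
    }
    vars <- nxt
  }
  vars
}

#' Simulate an EXB-tagged paired-end library
#'
#' Each molecule receives an independent EXB adapter per read end (subunit
#' indices and a 6-base random-mer each) and an insert; its full tagged
#' template (prefix1 + insert1, prefix2 + insert2) is amplified by branching
#' PCR with heritable per-base errors, `depth` read pairs are sampled with
#' replacement proportional to final copy numbers, and per-base sequencing
#' errors are applied. Reads never extend past the template (3'
#' read-through is not modeled).
#'
#' @param config An [sim_config()] object.
#' @param code An `exb_code` (default [build_code()]).
#' @param layout An `exb_layout` (default [build_layout()]).
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_R1.fastq.gz`, `<prefix>_R2.fastq.gz` and truth TSVs.
#' @return A list of class `exb_sim`: `reads` (data.table `read_id`, `seq1`,
#'   `seq2`), `truth` (list of data.tables `molecules` — `molecule_id`,
#'   `key`, `randmer`, `insert1`, `insert2` — and `reads` — `read_id`,
#'   `molecule_id`, `n_pcr_mut`, `n_seq_errors`, `seq_error_positions`),
#'   and `config`.
#' @export
simulate_library <- function(config, code = build_code(),
                             layout = build_layout(), out_prefix = NULL) {
  stopifnot(inherits(config, "exb_sim_config"))
  seeds <- .phase_seeds(config$seed)
  n <- config$n_fragments
  k <- length(code$barcodes)

  ## --- tagging ---------------------------------------------------------
  set.seed(seeds["tagging"])
  weights <- NULL
  if (config$label_weights == "lognormal") {
    sdlog <- sqrt(log(1 + config$label_cv^2))
    weights <- replicate(6, stats::rlnorm(k, 0, sdlog), simplify = FALSE)
  }
  slot_idx <- function(slot) {
    w <- if (is.null(weights)) NULL else weights[[slot]]
    if (is.null(w)) sample.int(k, n, replace = TRUE) - 1L
    else sample.int(k, n, replace = TRUE, prob = w) - 1L
  }
  idx <- vapply(1:6, slot_idx, integer(n))
  if (n == 1L) idx <- matrix(idx, nrow = 1L)
  randmer1 <- .random_dna(n, layout$randmer_len)
  randmer2 <- .random_dna(n, layout$randmer_len)
  keys <- apply(idx, 1L, .key_of)

  ## --- inserts ---------------------------------------------------------
  set.seed(seeds["inserts"])
  if (identical(config$insert_source, "random")) {
    insert1 <- .random_dna(n, config$insert_len)
    insert2 <- .random_dna(n, config$insert_len)
  } else {
    ref <- as.character(Biostrings::readDNAStringSet(config$insert_source))
    ref <- ref[nchar(ref) >= config$insert_len]
    if (length(ref) == 0L) stop("no reference sequence long enough")
    draw <- function() {
      s <- ref[sample.int(length(ref), 1L)]
      st <- sample.int(nchar(s) - config$insert_len + 1L, 1L)
      toupper(substr(s, st, st + config$insert_len - 1L))
    }
    insert1 <- replicate(n, draw())
    insert2 <- replicate(n, draw())
  }

  bc <- code$barcodes
  prefix1 <- paste0(randmer1, bc[idx[, 1] + 1L], layout$scaffolds[1],
                    bc[idx[, 2] + 1L], layout$scaffolds[2],
                    bc[idx[, 3] + 1L], layout$scaffolds[3], layout$me_seq)
  prefix2 <- paste0(randmer2, bc[idx[, 4] + 1L], layout$scaffolds[1],
                    bc[idx[, 5] + 1L], layout$scaffolds[2],
                    bc[idx[, 6] + 1L], layout$scaffolds[3], layout$me_seq)
  template <- paste0(prefix1, insert1, prefix2, insert2)
  tlen <- nchar(template[1])
  len1 <- layout$prefix_len + config$insert_len

  ## --- PCR -------------------------------------------------------------
  set.seed(seeds["pcr"])
  if (config$e_pcr > 0 || config$pcr_efficiency < 1) {
    fams <- lapply(seq_len(n), function(i)
      .pcr_family(tlen, config$cycles, config$pcr_efficiency, config$e_pcr))
    var_mol <- rep(seq_len(n), vapply(fams, length, integer(1)))
    var_list <- unlist(fams, recursive = FALSE)
    var_count <- vapply(var_list, `[[`, numeric(1), "count")
    var_seq <- vapply(seq_along(var_list), function(v) {
      pos <- var_list[[v]]$pos
      if (length(pos) == 0L) template[var_mol[v]]
      else .mutate_at(template[var_mol[v]], pos)
    }, character(1))
    var_nmut <- vapply(var_list, function(v) length(v$pos), integer(1))
  } else {
    var_mol <- seq_len(n)
    var_count <- rep(2^config$cycles, n)
    var_seq <- template
    var_nmut <- integer(n)
  }

  ## --- read sampling ---------------------------------------------------
  set.seed(seeds["sampling"])
  pick <- sample.int(length(var_count), config$depth, replace = TRUE,
                     prob = var_count)
  read_tpl <- var_seq[pick]
  read_mol <- var_mol[pick]

  ## --- sequencing errors ----------------------------------------------
  set.seed(seeds["seqerr"])
  n_err <- if (config$e_seq > 0)
    stats::rbinom(config$depth, tlen, config$e_seq) else integer(config$depth)
  err_pos <- vector("list", config$depth)
  for (i in which(n_err > 0L)) {
    p <- sample.int(tlen, n_err[i])
    err_pos[[i]] <- sort(p)
    read_tpl[i] <- .mutate_at(read_tpl[i], p)
  }

  rl <- min(config$read_len, len1)
  seq1 <- substr(read_tpl, 1L, rl)
  seq2 <- substr(read_tpl, len1 + 1L, len1 + rl)
  read_id <- sprintf("sim%07d", seq_len(config$depth))

  reads <- data.table::data.table(read_id = read_id, seq1 = seq1, seq2 = seq2)
  truth <- list(
    molecules = .dt_keyed(
      keys, molecule_id = seq_len(n),
      randmer = paste0(randmer1, randmer2),
      insert1 = insert1, insert2 = insert2),
    reads = data.table::data.table(
      read_id = read_id, molecule_id = read_mol,
      n_pcr_mut = var_nmut[pick], n_seq_errors = n_err,
      seq_error_positions = vapply(err_pos, function(p)
        paste(p, collapse = ","), character(1))))
  sim <- structure(list(reads = reads, truth = truth, config = config),
                   class = "exb_sim")
  if (!is.null(out_prefix)) write_sim(sim, out_prefix)
  sim
}

#' Write a simulated library to FASTQ and truth tables
#'
#' Emits gzip-compressed R1/R2 FASTQ (constant qualities), truth TSVs and a
#' small JSON-free run manifest recording the configuration.
#'
#' @param sim An `exb_sim` object.
#' @param out_prefix Path prefix for output files.
#' @return The FASTQ paths, invisibly.
#' @export
write_sim <- function(sim, out_prefix) {
  f1 <- paste0(out_prefix, "_R1.fastq.gz")
  f2 <- paste0(out_prefix, "_R2.fastq.gz")
  wq <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, compress = TRUE, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  }
  wq(sim$reads$seq1, paste0(sim$reads$read_id, "/1"), f1)
  wq(sim$reads$seq2, paste0(sim$reads$read_id, "/2"), f2)
  utils::write.table(sim$truth$molecules, paste0(out_prefix, "_molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$reads, paste0(out_prefix, "_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  manifest <- paste0(names(cfg), "=", vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)))
  writeLines(manifest, paste0(out_prefix, "_manifest.txt"))
  invisible(c(f1, f2))
}

#' Uniform-tagging abundance run
#'
#' Draws `n_reads` single-end labels uniformly from the 262,144-label space
#' and tabulates their abundances — the idealized counterpart of pooling
#' reads from a uniformly assembled adapter batch.
#'
#' @param n_reads Number of reads to draw (>= 1).
#' @param seed RNG seed.
#' @param n_labels Label-space size (default `64^3`).
#' @return A data.table with `label` (integer) and `count`, one row per
#'   observed label.
#' @export
uniform_tagging_run <- function(n_reads, seed = 1L, n_labels = 64^3) {
  stopifnot(n_reads >= 1)
  set.seed(seed)
  draws <- sample.int(n_labels, n_reads, replace = TRUE)
  tab <- tabulate(draws, nbins = n_labels)
  obs <- which(tab > 0L)
  data.table::data.table(label = obs, count = tab[obs])
}

#' Fraction of labels within one log10 of the median abundance
#'
#' @param counts Integer vector of per-label counts (observed labels only).
#' @return Fraction of labels with count in `[median/10, median*10]`.
#' @export
frac_within_log10 <- function(counts) {
  med <- stats::median(counts)
  mean(counts >= med / 10 & counts <= med * 10)
}

#' Monte-Carlo branching-PCR barcode-error probability
#'
#' Independent stochastic oracle for [pcr_error_prob()]: simulates the
#' per-cycle branching process (every copy present after a cycle receives
#' fresh Poisson error chances on its newly synthesized strand) and reports
#' the fraction of families with at least one barcode error.
#'
#' @param e Per-base substitution rate.
#' @param l Barcode length in bases.
#' @param c PCR cycles.
#' @param n_rep Number of simulated families.
#' @param efficiency Per-cycle duplication probability (default 1).
#' @return A list with `p_hat`, `se` (binomial standard error) and `n_rep`.
#' @export
pcr_branching_sim <- function(e, l, c, n_rep = 10000L, efficiency = 1) {
  p_any <- -expm1(l * log1p(-e))        # 1 - (1-e)^l
  clean <- rep(1, n_rep)
  flagged <- rep(FALSE, n_rep)
  for (cyc in seq_len(c)) {
    dup <- if (efficiency >= 1) clean else stats::rbinom(n_rep, clean, efficiency)
    exposed <- 2 * dup
    mut <- stats::rbinom(n_rep, exposed, p_any)
    flagged <- flagged | mut > 0L
    clean <- clean - dup + exposed - mut
  }
  p_hat <- mean(flagged)
  list(p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_rep), n_rep = n_rep)
}

#' Compare pipeline output with simulation ground truth
#'
#' Counts molecules by origin, without alignment: the EXB count is the
#' number of read groups, the random-mer-inflated count adds one per extra
#' distinct random-mer species per group, and assignment accuracy is the
#' fraction of assigned reads whose group key equals their originating
#' molecule's true key.
#'
#' @param groups An `exb_groups` object from the pipeline.
#' @param truth The `truth` element of an `exb_sim`.
#' @return A list of class `exb_count_report`: `exb_count`,
#'   `inflated_count`, `true_count`, `assignment_accuracy`, `n_discarded`.
#' @export
evaluate_counts <- function(groups, truth) {
  g <- groups$groups
  inflated <- sum(vapply(g$randmers, function(r) length(unique(r)),
                         integer(1)))
  asg <- merge(groups$assignments, truth$reads[, c("read_id", "molecule_id")],
               by = "read_id")
  asg <- merge(asg, truth$molecules[, c("molecule_id", "key")],
               by = "molecule_id", suffixes = c("", ".true"))
  if (nrow(asg) == 0L)
    warning("no read ids shared between assignments and truth; ",
            "pass the simulator's read ids to decode_reads()")
  acc <- mean(asg$key == asg$key.true)
  structure(list(exb_count = nrow(g), inflated_count = inflated,
                 true_count = nrow(truth$molecules),
                 assignment_accuracy = acc,
                 n_discarded = nrow(groups$discards)),
            class = "exb_count_report")
}

#' @export
print.exb_count_report <- function(x, ...) {
  cat("Molecule counts: true", x$true_count, "| EXB", x$exb_count,
      "| random-mer inflated", x$inflated_count,
      sprintf("| assignment accuracy %.4f | %d reads discarded\n",
              x$assignment_accuracy, x$n_discarded))
  invisible(x)
}
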