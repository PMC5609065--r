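# Characterization of random-mer (UMI) errors within EXB read groups. Every
# read carries a 12-base combined random-mer (6 per mate); since a read group
# holds PCR duplicates of one molecule, any disagreement among its
# random-mers is direct evidence of PCR or sequencing error.

# max pairwise Hamming distance among equal-length strings
.max_pairwise_hamming <- function(x) {
  u <- unique(x)
  if (length(u) == 1L) return(0L)
  mats <- strsplit(u, "", fixed = TRUE)
  best <- 0L
  for (i in seq_len(length(u) - 1L)) for (j in (i + 1L):length(u)) {
    d <- sum(mats[[i]] != mats[[j]])
    if (d > best) best <- d
  }
  as.integer(best)
}

#' Per-group random-mer statistics
#'
#' For every read group with more than one member (singleton groups carry no
#' duplicate information), counts the distinct 12-base random-mers, flags
#' discordance (more than one distinct sequence), and measures the maximum
#' pairwise substitution distance, overall and for each 6-base half
#' (read 1 / read 2). Distinct sequences are counted on exact identity —
#' the naive random-mer counting convention; random-mers containing N are
#' flagged so they can be excluded in sensitivity analyses.
#'
#' @param groups An `exb_groups` object.
#' @return A data.table of class `exb_randmer_stats` with columns `key`,
#'   `group_size`, `n_distinct`, `discordant`, `max_distance`,
#'   `n_distinct_r1`, `n_distinct_r2`, `max_distance_r1`, `max_distance_r2`,
#'   `has_n`.
#' @export
randmer_group_stats <- function(groups) {
  g <- groups$groups[groups$groups$size > 1L, ]
  if (nrow(g) == 0L) {
    out <- .dt_keyed(
      character(0), group_size = integer(0), n_distinct = integer(0),
      discordant = logical(0), max_distance = integer(0),
      n_distinct_r1 = integer(0), n_distinct_r2 = integer(0),
      max_distance_r1 = integer(0), max_distance_r2 = integer(0),
      has_n = logical(0))
    data.table::setattr(out, "class", c("exb_randmer_stats", class(out)))
    return(out)
  }
  half <- nchar(g$randmers[[1]][1]) %/% 2L
  stats_one <- function(rm) {
    r1 <- substr(rm, 1L, half)
    r2 <- substr(rm, half + 1L, 2L * half)
    list(n_distinct = length(unique(rm)),
         max_distance = .max_pairwise_hamming(rm),
         n_distinct_r1 = length(unique(r1)),
         n_distinct_r2 = length(unique(r2)),
         max_distance_r1 = .max_pairwise_hamming(r1),
         max_distance_r2 = .max_pairwise_hamming(r2),
         has_n = any(grepl("N", rm, fixed = TRUE)))
  }
  st <- lapply(g$randmers, stats_one)
  out <- .dt_keyed(
    g$key, group_size = g$size,
    n_distinct = vapply(st, `[[`, integer(1), "n_distinct"),
    max_distance = vapply(st, `[[`, integer(1), "max_distance"),
    n_distinct_r1 = vapply(st, `[[`, integer(1), "n_distinct_r1"),
    n_distinct_r2 = vapply(st, `[[`, integer(1), "n_distinct_r2"),
    max_distance_r1 = vapply(st, `[[`, integer(1), "max_distance_r1"),
    max_distance_r2 = vapply(st, `[[`, integer(1), "max_distance_r2"),
    has_n = vapply(st, `[[`, logical(1), "has_n"))
  out$discordant <- out$n_distinct > 1L
  data.table::setcolorder(out, c("key", "group_size", "n_distinct",
                                 "discordant", "max_distance"))
  data.table::setattr(out, "class", c("exb_randmer_stats", class(out)))
  out
}

#' Empirical discordance curve
#'
#' Fraction of read groups showing more than one distinct random-mer, as a
#' function of group size. Size bins with no groups are omitted.
#'
#' @param stats An `exb_randmer_stats` table.
#' @return A data.table with `group_size`, `n_groups`, `p_discordant`.
#' @export
discordance_curve <- function(stats) {
  stopifnot(nrow(stats) > 0L)
  out <- stats[, list(n_groups = .N, p_discordant = mean(discordant)),
               by = "group_size"]
  data.table::setorder(out, group_size)
  out
}

#' Distinct-count and distance curves over group size
#'
#' Mean and empirical 5/95% quantiles of the number of distinct random-mers
#' and of the maximum pairwise substitution distance, per group size.
#'
#' @param stats An `exb_randmer_stats` table.
#' @return A data.table with `group_size`, `n_groups`, and
#'   `mean`/`q05`/`q95` columns for `n_distinct` and `max_distance`.
#' @export
distinct_and_distance_curves <- function(stats) {
  stopifnot(nrow(stats) > 0L)
  out <- stats[, list(
    n_groups = .N,
    mean_n_distinct = mean(n_distinct),
    q05_n_distinct = unname(stats::quantile(n_distinct, 0.05, type = 1)),
    q95_n_distinct = unname(stats::quantile(n_distinct, 0.95, type = 1)),
    mean_max_distance = mean(max_distance),
    q05_max_distance = unname(stats::quantile(max_distance, 0.05, type = 1)),
    q95_max_distance = unname(stats::quantile(max_distance, 0.95, type = 1))),
    by = "group_size"]
  data.table::setorder(out, group_size)
  out
}

# number of distinct random-mers after optional single-linkage merging of
# sequences within Hamming distance <= merge_distance
.n_species <- function(rm, merge_distance = 0L) {
  u <- unique(rm)
  k <- length(u)
  if (merge_distance == 0L || k == 1L) return(k)
  mats <- strsplit(u, "", fixed = TRUE)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (sum(mats[[i]] != mats[[j]]) <= merge_distance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

#' Inflate consensus reads by distinct random-mers
#'
#' Emulates random-mer-based molecule counting: for every read group, emits
#' one consensus record per distinct random-mer observed in the group (all
#' records carry the group's EXB consensus sequence). With error-free
#' random-mers the output equals the EXB consensus set; every random-mer
#' error inflates the apparent molecule count. Setting `merge_distance = 1`
#' reproduces the common distance-1 random-mer correction before counting.
#'
#' @param groups An `exb_groups` object.
#' @param consensus The matching `exb_consensus` table (same keys).
#' @param merge_distance Hamming radius for single-linkage merging of
#'   random-mer species before counting (default 0, exact identity).
#' @return A data.table of class `exb_consensus` with one row per
#'   (group, random-mer species): columns `key`, `species`, `seq1`, `seq2`.
#' @export
inflate_consensus <- function(groups, consensus, merge_distance = 0L) {
  g <- groups$groups
  n_sp <- vapply(g$randmers, .n_species, integer(1),
                 merge_distance = merge_distance)
  idx <- match(g$key, consensus$key)
  keep <- !is.na(idx)
  rep_idx <- rep(which(keep), n_sp[keep])
  out <- .dt_keyed(
    g$key[rep_idx],
    species = unlist(lapply(n_sp[keep], seq_len)),
    seq1 = consensus$seq1[idx[rep_idx]],
    seq2 = consensus$seq2[idx[rep_idx]])
  data.table::setattr(out, "class", c("exb_consensus", class(out)))
  out
}
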