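# Versioned key-value configuration shared by the codec and adapter modules.

.CONFIG_VERSION <- "1"

# Frozen default generator matrix, 18 base characters row-major. Selected by
# exhaustive search over all standard-form [I3 | P] matrices over GF(4)
# (see search_generator_matrices): the lexicographically smallest P whose
# code reaches the maximal minimum distance 4.
.DEFAULT_GENERATOR <- "CAACCCACACGTAACCTG"

# Fixed scaffold sequences separating the three barcode subunits. Lengths
# 10/9/9 so that 6 (random-mer) + 3*6 (subunits) + 28 (scaffolds) + 19 (ME)
# = 71 bases of inline prefix. Sequences are synthetic conventions with
# near-balanced GC, overridable in the config.
.DEFAULT_SCAFFOLDS <- c("ACGTGATCGT", "TGCATCGAG", "CATGCTAGC")

# Tn5 mosaic-end recognition sequence on the top strand of the adapter; its
# reverse complement (CTGTCTCTTATACACATCT) is the 3' read-through trim target.
.ME_SEQ <- "AGATGTGTATAAGAGACAG"

#' Default EXB configuration
#'
#' Bundles the generator matrix of the barcode code and the adapter geometry
#' (random-mer length, scaffold sequences, transposase recognition sequence,
#' read length) into a single overridable configuration object.
#'
#' @param generator 18 DNA characters, the 3x6 generator matrix row-major
#'   under the A=0, C=1, G=2, T=3 symbol mapping. Must be in standard form
#'   `[I3 | P]`.
#' @param scaffolds Character vector of three scaffold sequences inserted
#'   after subunits 1, 2 and 3.
#' @param me_seq The 19-base transposase recognition sequence terminating the
#'   inline prefix (top strand).
#' @param randmer_len Length in bases of the random-mer at the start of each
#'   read (default 6; both mates carry one, 12 bases combined).
#' @param read_len Sequencing read length in bases (default 151).
#' @return An object of class `exb_config` (a named list).
#' @examples
#' cfg <- exb_config()
#' nchar(cfg$generator)  # 18
#' @export
exb_config <- function(generator = .DEFAULT_GENERATOR,
                       scaffolds = .DEFAULT_SCAFFOLDS,
                       me_seq = .ME_SEQ,
                       randmer_len = 6L,
                       read_len = 151L) {
  stopifnot(nchar(generator) == 18L, length(scaffolds) == 3L,
            randmer_len >= 0L, read_len >= 1L)
  if (grepl("[^ACGT]", generator) || any(grepl("[^ACGT]", scaffolds)) ||
      grepl("[^ACGT]", me_seq))
    stop("configuration sequences must contain only A/C/G/T")
  structure(list(generator = generator,
                 scaffolds = toupper(scaffolds),
                 me_seq = toupper(me_seq),
                 randmer_len = as.integer(randmer_len),
                 read_len = as.integer(read_len),
                 version = .CONFIG_VERSION),
            class = "exb_config")
}

#' Write an EXB configuration file
#'
#' Plain-text `key=value` format with a version line; round-trips through
#' [read_exb_config()].
#'
#' @param config An `exb_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exb_config <- function(config, path) {
  stopifnot(inherits(config, "exb_config"))
  lines <- c(paste0("version=", config$version),
             paste0("generator=", config$generator),
             paste0("scaffold_a=", config$scaffolds[1]),
             paste0("scaffold_b=", config$scaffolds[2]),
             paste0("scaffold_c=", config$scaffolds[3]),
             paste0("me_seq=", config$me_seq),
             paste0("randmer_len=", config$randmer_len),
             paste0("read_len=", config$read_len))
  writeLines(lines, path)
  invisible(path)
}

#' Read an EXB configuration file
#'
#' @param path Path to a file written by [write_exb_config()].
#' @return An `exb_config` object.
#' @export
read_exb_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  if (!identical(unname(vals["version"]), .CONFIG_VERSION))
    stop("unsupported config version: ", vals["version"])
  exb_config(generator = vals[["generator"]],
             scaffolds = unname(vals[c("scaffold_a", "scaffold_b", "scaffold_c")]),
             me_seq = vals[["me_seq"]],
             randmer_len = as.integer(vals[["randmer_len"]]),
             read_len = as.integer(vals[["read_len"]]))
}
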