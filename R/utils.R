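#' @import data.table
#' @importFrom stats pbinom rbinom rpois rbeta rnorm rlnorm sd wilcox.test
#' @importFrom utils head tail
NULL

# Internal coordinates are 0-based half-open everywhere; 1-based formats
# (VCF, SAM, GFF3) are converted at the read/write boundary.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Plain-character helper for short sequences (codons, small fixtures).
#'
#' @param x character vector of DNA strings (A/C/G/T, case preserved only
#'   for upper case input).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Derive a reproducible sub-seed
#'
#' Maps a base seed and a short tag to a distinct seed below 2^31, so that
#' independent simulation stages can each seed the RNG deterministically.
#'
#' @param seed integer base seed.
#' @param tag character tag naming the consumer.
#' @return a single integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483647)
}

#' Write a table as TSV
#'
#' Tab-separated, header line, no quoting, NA written as "NA".  Numeric
#' columns are written with full precision so that a write/read round trip
#' is exact.
#'
#' @param x data.frame or data.table.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA",
                     scipen = 50)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return a data.table.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                    data.table = TRUE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0
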