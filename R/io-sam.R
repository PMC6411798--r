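# Plain-text SAM reader for RNA alignments.  Only the fields the allele
# counter uses are retained; unmapped reads are skipped and tallied.

SAM_FLAG_UNMAPPED      <- 0x4L
SAM_FLAG_SECONDARY     <- 0x100L
SAM_FLAG_DUPLICATE     <- 0x400L
SAM_FLAG_SUPPLEMENTARY <- 0x800L

cigar_ops <- function(cigar) {
  # returns list(len = integer vector, op = character vector)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || !length(ops))
    stopf("malformed CIGAR: %s", cigar)
  list(len = lens, op = ops)
}

cigar_query_length <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "I", "S", "=", "X")])
}

#' Read a text SAM file
#'
#' @param path path to a SAM v1 text file with header.
#' @return a data.table of mapped reads with columns `qname`, `flag`,
#'   `chrom`, `pos0` (0-based leftmost), `mapq`, `cigar`, `seq`, `qual`
#'   (Phred+33 string); attribute `n_unmapped` counts skipped unmapped
#'   reads.  A CIGAR whose consumed query length disagrees with the
#'   sequence length is an error naming the read.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  n_unmapped <- 0L
  rows <- vector("list", length(lines))
  kept <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stopf("SAM record with <11 fields: %s", f[1])
    flag <- as.integer(f[2])
    if (bitwAnd(flag, SAM_FLAG_UNMAPPED) != 0L) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    if (f[10] != "*" && f[6] != "*" &&
        cigar_query_length(f[6]) != nchar(f[10]))
      stopf("read %s: CIGAR %s consumes %d query bases but SEQ has %d",
            f[1], f[6], cigar_query_length(f[6]), nchar(f[10]))
    kept <- kept + 1L
    rows[[kept]] <- list(qname = f[1], flag = flag, chrom = f[3],
                         pos0 = as.integer(f[4]) - 1L, mapq = as.integer(f[5]),
                         cigar = f[6], seq = f[10], qual = f[11])
  }
  out <- if (kept) data.table::rbindlist(rows[seq_len(kept)]) else
    data.table::data.table(qname = character(), flag = integer(),
                           chrom = character(), pos0 = integer(),
                           mapq = integer(), cigar = character(),
                           seq = character(), qual = character())
  data.table::setattr(out, "n_unmapped", n_unmapped)
  out[]
}

#' Write reads as text SAM
#'
#' @param reads data.table in the layout returned by [read_sam()].
#' @param path output path.
#' @param seqinfo named integer vector of chromosome lengths for `@SQ` lines.
#' @return invisibly, `path`.
#' @export
write_sam <- function(reads, path, seqinfo) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo),
                       as.integer(seqinfo))), con, sep = "\n")
  if (nrow(reads))
    writeLines(paste(reads$qname, reads$flag, reads$chrom, reads$pos0 + 1L,
                     reads$mapq, reads$cigar, "*", 0L, 0L, reads$seq,
                     reads$qual, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Map a reference position to the query offset of a read
#'
#' Walks the CIGAR string from the read's leftmost mapped position.
#'
#' @param cigar CIGAR string.
#' @param read_pos0 0-based leftmost reference position of the read.
#' @param ref_pos0 0-based reference position of interest.
#' @return 0-based query offset, or NA if the position falls in a deletion
#'   (`D`), a skipped region (`N`), or outside the aligned span.
#' @export
query_offset_at <- function(cigar, read_pos0, ref_pos0) {
  co <- cigar_ops(cigar)
  rpos <- read_pos0
  qpos <- 0L
  for (k in seq_along(co$op)) {
    op <- co$op[k]; len <- co$len[k]
    if (op %in% c("M", "=", "X")) {
      if (ref_pos0 >= rpos && ref_pos0 < rpos + len)
        return(qpos + (ref_pos0 - rpos))
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (ref_pos0 >= rpos && ref_pos0 < rpos + len) return(NA_integer_)
      rpos <- rpos + len
    }  # H, P consume nothing
  }
  NA_integer_
}
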