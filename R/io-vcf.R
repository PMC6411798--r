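# VCF reader/writer restricted to what the pipeline consumes: biallelic SNPs
# with GT genotypes.  Indel / multiallelic records are skipped and tallied in
# a parse report rather than parsed, because every downstream statistic
# (discriminating-SNP assignment, Fst, Hp, allele counting) is defined on
# biallelic SNPs only.

#' Container for VCF variant sites
#'
#' @param sites data.table with columns `chrom`, `pos0` (0-based), `ref`,
#'   `alt`, `qual`.
#' @param geno integer matrix, sites x samples, alternate-allele dosage
#'   (0, 1, 2 or NA for missing).
#' @param samples data.table with columns `sample`, `population`.
#' @param report list of parse tallies.
#' @return an object of class `variant_sites`.
#' @export
variant_sites <- function(sites, geno, samples,
                          report = list(n_kept = nrow(sites),
                                        n_skipped = 0L, skipped = integer())) {
  sites <- data.table::as.data.table(sites)
  stopifnot(all(c("chrom", "pos0", "ref", "alt", "qual") %in% names(sites)),
            nrow(sites) == nrow(geno), nrow(samples) == ncol(geno))
  if (nrow(sites)) {
    if (any(sites$pos0 < 0)) stopf("negative position")
    if (any(sites$ref == sites$alt)) stopf("ref == alt at some site")
    if (!all(c(sites$ref, sites$alt) %in% DNA_BASES))
      stopf("non-SNP allele in variant_sites")
  }
  structure(list(sites = sites, geno = geno,
                 samples = data.table::as.data.table(samples),
                 report = report),
            class = "variant_sites")
}

#' @export
print.variant_sites <- function(x, ...) {
  cat(sprintf("<variant_sites> %d biallelic SNPs x %d samples (%s)\n",
              nrow(x$sites), nrow(x$samples),
              paste(sprintf("%s:%d", unique(x$samples$population),
                            tabulate(factor(x$samples$population,
                                            unique(x$samples$population)))),
                    collapse = ", ")))
  if (x$report$n_skipped > 0)
    cat(sprintf("  skipped %d records (%s)\n", x$report$n_skipped,
                paste(names(x$report$skipped), x$report$skipped,
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Number of sites
#' @param x variant_sites object.
#' @return integer count of retained sites.
#' @export
n_sites <- function(x) nrow(x$sites)

parse_gt <- function(gt) {
  # "0/1", "0|1", "./." -> alt dosage; phase is ignored by design
  gt <- sub(":.*", "", gt)
  a <- substr(gt, 1L, 1L)
  b <- substr(gt, 3L, 3L)
  out <- rep(NA_integer_, length(gt))
  ok <- a %in% c("0", "1") & b %in% c("0", "1")
  out[ok] <- (a[ok] == "1") + (b[ok] == "1")
  out
}

#' Read a VCF file of biallelic SNPs
#'
#' Only `GT` is consumed from the FORMAT column.  Indel and multiallelic
#' records are skipped and tallied; phased (`0|1`) and unphased (`0/1`)
#' genotypes are treated identically; any genotype containing `.` is
#' missing.
#'
#' @param path path to an uncompressed VCF v4.x file.
#' @param population_map named character vector mapping sample name to a
#'   population label (e.g. `c(Y1 = "YUNLING", N1 = "NUBIAN")`).  Every name
#'   must be present in the VCF header; header samples not in the map are
#'   dropped.
#' @return a [variant_sites()] object; `$report` tallies skipped records.
#' @export
read_vcf <- function(path, population_map) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM\t", lines)
  if (length(hdr_i) != 1L) stopf("%s: no #CHROM header line", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) stopf("%s: VCF has no sample columns", path)
  vcf_samples <- hdr[-(1:9)]
  missing_samp <- setdiff(names(population_map), vcf_samples)
  if (length(missing_samp))
    stopf("samples in population_map absent from VCF header: %s",
          paste(missing_samp, collapse = ", "))
  keep_samp <- match(names(population_map), vcf_samples)

  body_i <- seq(hdr_i + 1L, length.out = length(lines) - hdr_i)
  skipped <- c(indel = 0L, multiallelic = 0L, no_gt = 0L, monomorphic = 0L)
  rows <- vector("list", length(body_i))
  genos <- vector("list", length(body_i))
  kept <- 0L
  for (i in body_i) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stopf("%s line %d: expected %d fields, got %d", path, i,
            length(hdr), length(f))
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt, fixed = TRUE)) { skipped["multiallelic"] <- skipped["multiallelic"] + 1L; next }
    if (alt == "." || alt == ref) { skipped["monomorphic"] <- skipped["monomorphic"] + 1L; next }
    if (nchar(ref) != 1L || nchar(alt) != 1L ||
        !(ref %in% DNA_BASES) || !(alt %in% DNA_BASES)) {
      skipped["indel"] <- skipped["indel"] + 1L; next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    if (!("GT" %in% fmt)) { skipped["no_gt"] <- skipped["no_gt"] + 1L; next }
    if (fmt[1] != "GT")
      stopf("%s line %d: GT must be the first FORMAT key", path, i)
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) stopf("%s line %d: bad POS '%s'", path, i, f[2])
    qual <- suppressWarnings(as.numeric(f[6]))
    kept <- kept + 1L
    rows[[kept]] <- list(chrom = f[1], pos0 = pos - 1L, ref = ref, alt = alt,
                         qual = qual)
    genos[[kept]] <- parse_gt(f[9 + keep_samp])
  }
  sites <- if (kept) data.table::rbindlist(rows[seq_len(kept)]) else
    data.table::data.table(chrom = character(), pos0 = integer(),
                           ref = character(), alt = character(),
                           qual = numeric())
  geno <- if (kept) do.call(rbind, genos[seq_len(kept)]) else
    matrix(integer(), 0L, length(keep_samp))
  colnames(geno) <- names(population_map)
  variant_sites(sites, geno,
                data.table::data.table(sample = names(population_map),
                                       population = unname(population_map)),
                report = list(n_kept = kept, n_skipped = sum(skipped),
                              skipped = skipped))
}

#' Write variant sites as VCF
#'
#' Emits a minimal VCF v4.2 with GT-only genotypes; byte-deterministic for a
#' given object.
#'
#' @param vs a [variant_sites()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(vs, path) {
  con <- file(path, "wb")  # "wb": identical bytes on every platform
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vs$samples$sample), collapse = "\t")),
             con, sep = "\n")
  if (!nrow(vs$sites)) return(invisible(path))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vs$geno + 1L], nrow = nrow(vs$geno))
  gt_str[is.na(vs$geno)] <- "./."
  body <- paste(vs$sites$chrom, vs$sites$pos0 + 1L, ".", vs$sites$ref,
                vs$sites$alt, formatC(vs$sites$qual, format = "fg"),
                "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Subset variant sites by row index
#' @param vs variant_sites object.
#' @param idx integer or logical index over sites.
#' @return a variant_sites object with the selected sites.
#' @export
subset_sites <- function(vs, idx) {
  variant_sites(vs$sites[idx], vs$geno[idx, , drop = FALSE], vs$samples,
                report = vs$report)
}
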