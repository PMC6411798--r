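# GFF3 gene models.  Multi-transcript genes are collapsed to the union of
# their exons plus the CDS set of the transcript with the longest total
# coding length, because all downstream reporting is gene-level.

parse_gff_attrs <- function(attr) {
  # "ID=x;Parent=y;biotype=z" -> named character vector
  kv <- strsplit(strsplit(attr, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, 0L) == 2L]
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

merge_intervals <- function(start, end) {
  # 0-based half-open union of intervals
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  data.table::data.table(start = c(out_s, ms), end = c(out_e, me))
}

#' Gene models container
#'
#' @param genes data.table: `gene_id`, `chrom`, `strand`, `biotype`,
#'   `start`, `end` (0-based half-open gene span).
#' @param exons data.table: `gene_id`, `start`, `end` (exon union, sorted,
#'   non-overlapping).
#' @param cds data.table: `gene_id`, `start`, `end`, `frame` (phase of the
#'   first base of the interval on the coding strand).
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds) {
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  cds <- data.table::as.data.table(cds)
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$biotype %in% c("protein_coding", "noncoding_RNA",
                                     "pseudogene")))
  if (nrow(cds) && !all(cds$frame %in% 0:2)) stopf("CDS frame must be 0/1/2")
  data.table::setkey(genes, chrom, start)
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes (%d with CDS) on %d sequence(s)\n",
              nrow(x$genes), length(unique(x$cds$gene_id)),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Expects gene / mRNA (or transcript) / exon / CDS features linked by
#' `Parent` attributes.  A `biotype` (or `gene_biotype`) attribute on the
#' gene feature is honoured; anything other than a known biotype defaults
#' to `protein_coding`.
#'
#' @param path GFF3 file path.
#' @return a [gene_models()] object (internal 0-based half-open coordinates).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- gene_models(
    data.table::data.table(gene_id = character(), chrom = character(),
                           strand = character(), biotype = character(),
                           start = integer(), end = integer()),
    data.table::data.table(gene_id = character(), start = integer(),
                           end = integer()),
    data.table::data.table(gene_id = character(), start = integer(),
                           end = integer(), frame = integer()))
  if (!length(lines)) return(empty)
  f <- data.table::as.data.table(
    do.call(rbind, strsplit(lines, "\t", fixed = TRUE)))
  data.table::setnames(f, c("chrom", "source", "type", "start", "end",
                            "score", "strand", "phase", "attr"))
  f[, `:=`(start = as.integer(start) - 1L, end = as.integer(end))]
  attrs <- lapply(f$attr, parse_gff_attrs)
  f[, id := vapply(attrs, function(a) a["ID"] %||% NA_character_, "")]
  f[, parent := vapply(attrs, function(a) a["Parent"] %||% NA_character_, "")]

  genes_f <- f[type == "gene"]
  biotype <- vapply(attrs[f$type == "gene"], function(a) {
    b <- a["biotype"]
    if (is.na(b)) b <- a["gene_biotype"]
    if (is.na(b) || !(b %in% c("protein_coding", "noncoding_RNA",
                               "pseudogene"))) "protein_coding" else unname(b)
  }, "")
  if (anyNA(genes_f$id)) stopf("gene feature without ID attribute")
  genes <- data.table::data.table(
    gene_id = genes_f$id, chrom = genes_f$chrom, strand = genes_f$strand,
    biotype = biotype, start = genes_f$start, end = genes_f$end)

  # transcript -> gene resolution
  tx <- f[type %in% c("mRNA", "transcript")]
  tx2gene <- stats::setNames(tx$parent, tx$id)
  if (any(!(tx2gene %in% genes$gene_id)))
    stopf("transcript with Parent not matching any gene")
  resolve_gene <- function(parent, what) {
    out <- ifelse(parent %in% genes$gene_id, parent,
                  unname(tx2gene[parent]))
    bad <- is.na(out) | !(out %in% genes$gene_id)
    if (any(bad))
      stopf("%s feature whose Parent '%s' resolves to no gene", what,
            parent[bad][1])
    out
  }

  exons_f <- f[type == "exon"]
  exons <- if (nrow(exons_f)) {
    exons_f[, gene_id := resolve_gene(parent, "exon")]
    exons_f[, merge_intervals(start, end), by = gene_id]
  } else empty$exons

  cds_f <- f[type == "CDS"]
  cds <- if (nrow(cds_f)) {
    cds_f[, gene_id := resolve_gene(parent, "CDS")]
    cds_f[, tx_id := ifelse(parent %in% genes$gene_id, parent, parent)]
    # longest-CDS transcript per gene
    cds_f[, cds_len := sum(end - start), by = .(gene_id, parent)]
    cds_f <- cds_f[, .SD[cds_len == max(cds_len)][parent == parent[1]],
                   by = gene_id]
    out <- cds_f[, .(gene_id, start, end, frame = as.integer(phase))]
    data.table::setorder(out, gene_id, start)
    out[]
  } else empty$cds

  gene_models(genes, exons, cds)
}

#' Write gene models as GFF3
#'
#' One mRNA per gene (the collapsed model); exon and CDS children carry
#' `Parent` attributes.  Byte-deterministic.
#'
#' @param gm a [gene_models()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(gm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  g <- gm$genes[order(chrom, start)]
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       gid, g$biotype[i]), con, sep = "\n")
    writeLines(sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       gid, gid), con, sep = "\n")
    ex <- gm$exons[gene_id == gid][order(start)]
    if (nrow(ex))
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
                         g$chrom[i], ex$start + 1L, ex$end, g$strand[i], gid),
                 con, sep = "\n")
    cd <- gm$cds[gene_id == gid][order(start)]
    if (nrow(cd))
      writeLines(sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s.t1",
                         g$chrom[i], cd$start + 1L, cd$end, g$strand[i],
                         cd$frame, gid), con, sep = "\n")
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param x data.table with at least `chrom`, `start`, `end`; extra columns
#'   are appended after the name field.
#' @param path output path.
#' @param name optional column to place in the BED name field.
#' @return invisibly, `path`.
#' @export
write_bed <- function(x, path, name = NULL) {
  x <- data.table::as.data.table(x)
  nm <- if (!is.null(name)) x[[name]] else "."
  bed <- data.table::data.table(chrom = x$chrom, start = x$start,
                                end = x$end, name = nm)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
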