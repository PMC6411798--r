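# Core-ASE genes: the intersection of ASE genes with genes in selective
# sweep regions, plus the ASE vs non-ASE expression comparison and the
# final report bundle.

#' Intersect ASE genes with sweep-region genes
#'
#' A gene is core-ASE when it shows ASE in at least one tissue and overlaps
#' at least one sweep region under any of the three criteria (high ZFst,
#' low ZHp in either population).
#'
#' @param gene_ase gene-level ASE table (after imprint exclusion).
#' @param regions sweep regions from [genes_in_regions()] /
#'   [run_sweep_scan()] (`regions` element).
#' @param region_genes region/gene pairs (`region_genes` element).
#' @return list with `core` (gene_id, n_tissues, tissues, criteria,
#'   peak_z) and `matrix` (genes x tissues logical presence table).
#' @export
intersect_core_ase <- function(gene_ase, regions, region_genes) {
  gene_ase <- data.table::as.data.table(gene_ase)
  ase <- gene_ase[is_ase_gene == TRUE,
                  .(tissues = paste(sort(unique(tissue)), collapse = ";"),
                    n_tissues = data.table::uniqueN(tissue)),
                  by = gene_id]
  if (nrow(region_genes)) {
    ev <- data.table::as.data.table(region_genes)
    ev[, `:=`(criterion = regions$criterion[region],
              peak_z = regions$peak_z[region])]
    ev <- ev[, .(criteria = paste(sort(unique(criterion)), collapse = ";"),
                 peak_z = peak_z[which.max(abs(peak_z))]), by = gene_id]
  } else {
    ev <- data.table::data.table(gene_id = character(),
                                 criteria = character(), peak_z = numeric())
  }
  core <- merge(ase, ev, by = "gene_id")
  data.table::setorder(core, -n_tissues, gene_id)

  tissues <- sort(unique(gene_ase$tissue))
  mat <- data.table::data.table(gene_id = core$gene_id)
  for (t in tissues) {
    in_t <- gene_ase[tissue == t & is_ase_gene == TRUE, gene_id]
    mat[, (t) := gene_id %in% in_t]
  }
  list(core = core[], matrix = mat[])
}

#' Compare expression of ASE vs non-ASE genes
#'
#' Genes whose mean FPKM exceeds `fpkm_threshold` are partitioned into ASE
#' and non-ASE; group means and a two-sided Wilcoxon rank-sum p-value are
#' reported (the comparison the "ASE genes are higher expressed" claim
#' rests on; a rank test avoids the heavy right tail of FPKM).
#'
#' @param expression data.table `gene_id`, `sample`, `fpkm` (one tissue's
#'   samples, or any sample set forming one comparison).
#' @param ase_genes character vector of ASE gene ids.
#' @param fpkm_threshold expression floor (default 0.01, strict `>`).
#' @return list: mean_ase, mean_non_ase, n_ase, n_non_ase, p_value (NA when
#'   either group has < 2 genes).
#' @export
expression_comparison <- function(expression, ase_genes,
                                  fpkm_threshold = 0.01) {
  expression <- data.table::as.data.table(expression)
  gene_mean <- expression[, .(fpkm = mean(fpkm)), by = gene_id]
  gene_mean <- gene_mean[fpkm > fpkm_threshold]
  if (!nrow(gene_mean)) {
    warning("no genes above the FPKM threshold")
    return(list(mean_ase = NA_real_, mean_non_ase = NA_real_, n_ase = 0L,
                n_non_ase = 0L, p_value = NA_real_))
  }
  is_ase <- gene_mean$gene_id %in% ase_genes
  x <- gene_mean$fpkm[is_ase]
  y <- gene_mean$fpkm[!is_ase]
  p <- if (length(x) >= 2L && length(y) >= 2L)
    stats::wilcox.test(x, y, exact = FALSE)$p.value else NA_real_
  list(mean_ase = if (length(x)) mean(x) else NA_real_,
       mean_non_ase = if (length(y)) mean(y) else NA_real_,
       n_ase = length(x), n_non_ase = length(y), p_value = p)
}

#' Gene biotype tally of the final ASE gene set
#'
#' @param ase_genes character vector of gene ids.
#' @param gm a [gene_models()] object.
#' @return data.table `biotype`, `n`.
#' @export
gene_biotype_summary <- function(ase_genes, gm) {
  bt <- gm$genes[gene_id %in% ase_genes, biotype]
  lv <- c("protein_coding", "noncoding_RNA", "pseudogene")
  data.table::data.table(biotype = lv,
                         n = as.integer(table(factor(bt, lv))))
}

#' Per-SNP, per-individual allele display for one gene
#'
#' @param site_calls site-level calls from [call_ase_sites()].
#' @param gene gene id.
#' @return the gene's rows: site, individual, tissue, line counts, ratio,
#'   q, call.
#' @export
gene_allele_table <- function(site_calls, gene) {
  site_calls <- data.table::as.data.table(site_calls)
  cols <- intersect(c("chrom", "pos0", "gene_id", "individual", "tissue",
                      "n_line_a", "n_line_b", "ratio", "p_value", "q_value",
                      "is_ase"), names(site_calls))
  out <- site_calls[gene_id == gene, ..cols]
  data.table::setorder(out, chrom, pos0, tissue, individual)
  out[]
}
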