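# Allele-specific expression at F1-heterozygous discriminating SNPs:
# per-site allele counting from RNA alignments, replicate pooling, depth
# filters, exact two-sided binomial test of the line-A read fraction
# against 0.5, Benjamini-Hochberg FDR, site- and gene-level calls, and
# imprinted-gene exclusion.

#' Extract allele counts at SNP sites from aligned reads
#'
#' For each read overlapping a site: the read is skipped if its unmapped,
#' secondary, supplementary or duplicate flag is set, if `mapq <
#' min_mapq`, or if the base quality at the site is below `min_baseq`; the
#' CIGAR is walked to locate the query offset of the site (positions under
#' a deletion or N segment contribute nothing); the base increments
#' `n_ref`, `n_alt` or `n_other`.
#'
#' @param reads read table from [read_sam()].
#' @param sites data.table with `chrom`, `pos0`, `ref`, `alt` (plus any
#'   carried columns, e.g. `gene_id`, `allele_a`).
#' @param min_mapq minimum mapping quality (default 20).
#' @param min_baseq minimum base quality at the site (default 20).
#' @return `sites` with `n_ref`, `n_alt`, `n_other` appended; attribute
#'   `n_missing_chrom` counts sites on chromosomes absent from the
#'   alignments (reported with zero counts, with a warning).
#' @export
extract_allele_counts <- function(reads, sites, min_mapq = 20L,
                                  min_baseq = 20L) {
  sites <- data.table::as.data.table(sites)
  usable <- reads[bitwAnd(flag, SAM_FLAG_SECONDARY + SAM_FLAG_DUPLICATE +
                            SAM_FLAG_SUPPLEMENTARY) == 0L & mapq >= min_mapq]
  n_ref <- n_alt <- n_other <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cand <- usable[chrom == sites$chrom[i] & pos0 <= sites$pos0[i] &
                     pos0 + nchar(seq) + 1000L > sites$pos0[i]]
    for (j in seq_len(nrow(cand))) {
      qoff <- query_offset_at(cand$cigar[j], cand$pos0[j], sites$pos0[i])
      if (is.na(qoff)) next
      bq <- utf8ToInt(substr(cand$qual[j], qoff + 1L, qoff + 1L)) - 33L
      if (length(bq) && bq < min_baseq) next
      base <- substr(cand$seq[j], qoff + 1L, qoff + 1L)
      if (base == sites$ref[i]) n_ref[i] <- n_ref[i] + 1L
      else if (base == sites$alt[i]) n_alt[i] <- n_alt[i] + 1L
      else n_other[i] <- n_other[i] + 1L
    }
  }
  out <- data.table::copy(sites)
  out[, `:=`(n_ref = n_ref, n_alt = n_alt, n_other = n_other)]
  missing_chrom <- !(sites$chrom %in% unique(reads$chrom))
  if (any(missing_chrom))
    warning(sum(missing_chrom),
            " site(s) on chromosomes absent from the alignments")
  data.table::setattr(out, "n_missing_chrom", sum(missing_chrom))
  out[]
}

#' Relabel ref/alt counts by parental line of origin
#'
#' @param counts table with `n_ref`, `n_alt` and the discriminating
#'   alleles `ref`, `allele_a`.
#' @return `counts` with `n_line_a`, `n_line_b` appended.
#' @export
counts_by_line <- function(counts) {
  counts <- data.table::copy(data.table::as.data.table(counts))
  a_is_ref <- counts$allele_a == counts$ref
  counts[, `:=`(n_line_a = ifelse(a_is_ref, n_ref, n_alt),
                n_line_b = ifelse(a_is_ref, n_alt, n_ref))]
  counts[]
}

#' Pool technical replicates
#'
#' @param counts allele-count table with a `replicate` column.
#' @param scheme `"sum"` adds counts across replicates of the same (site,
#'   individual, tissue); `"separate"` leaves rows untouched.
#' @return pooled table (no `replicate` column under `"sum"`).
#' @export
pool_replicates <- function(counts, scheme = c("sum", "separate")) {
  scheme <- match.arg(scheme)
  counts <- data.table::as.data.table(counts)
  if (scheme == "separate") return(data.table::copy(counts))
  cnt_cols <- intersect(c("n_ref", "n_alt", "n_other", "n_line_a",
                          "n_line_b"), names(counts))
  by_cols <- setdiff(names(counts), c(cnt_cols, "replicate"))
  counts[, lapply(.SD, sum), by = by_cols, .SDcols = cnt_cols]
}

#' Apply the read-depth filters
#'
#' `literal` mode keeps a site iff each line's allele depth is at least
#' `min_allele_depth` AND the total is at least `min_total_depth` (so the
#' published "individual allele read depth <20 and total read depth <50
#' filtered out" boundaries: 19 fails, 20 passes; total 50 passes).
#' `major` mode requires only the deeper allele to reach
#' `min_allele_depth`, which preserves strongly imbalanced (including
#' near-monoallelic) sites that `literal` mode discards.
#'
#' @param counts pooled allele-count table with `n_line_a`, `n_line_b`.
#' @param min_allele_depth per-allele depth threshold (default 20).
#' @param min_total_depth total depth threshold (default 50).
#' @param mode `"literal"` or `"major"`.
#' @return the retained rows; attribute `n_filtered` counts removals.
#' @export
filter_counts <- function(counts, min_allele_depth = 20L,
                          min_total_depth = 50L,
                          mode = c("literal", "major")) {
  mode <- match.arg(mode)
  counts <- data.table::as.data.table(counts)
  total <- counts$n_line_a + counts$n_line_b
  allele_ok <- if (mode == "literal")
    pmin(counts$n_line_a, counts$n_line_b) >= min_allele_depth
  else pmax(counts$n_line_a, counts$n_line_b) >= min_allele_depth
  keep <- allele_ok & total >= min_total_depth
  out <- counts[keep]
  data.table::setattr(out, "n_filtered", sum(!keep))
  out[]
}

#' Two-sided exact binomial test against 0.5
#'
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` with `X ~ Binomial(n, 1/2)`;
#' for the symmetric null this equals the minimum-likelihood two-sided
#' construction.  Vectorised.
#'
#' @param n_a,n_b non-negative counts; `n_a + n_b >= 1`.
#' @return two-sided p-value(s) in (0, 1].
#' @export
binomial_test <- function(n_a, n_b) {
  if (any(n_a + n_b < 1L)) stopf("binomial_test: both counts are zero")
  n <- n_a + n_b
  lower <- stats::pbinom(n_a, n, 0.5)
  upper <- stats::pbinom(n_a - 1L, n, 0.5, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, mapped back to the
#' input order.
#'
#' @param p p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p) | p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1L)))[ro]
}

#' Call ASE at the site level
#'
#' Tests each (site, individual, tissue) row's line-A fraction against 0.5,
#' BH-adjusts within the chosen FDR family, and calls ASE when `q <
#' q_threshold` and the ratio is strictly outside (`ratio_lo`,
#' `ratio_hi`).  A ratio of exactly `ratio_hi` (0.7) or `ratio_lo` (0.3)
#' is never called.
#'
#' @param counts filtered allele-count table with `n_line_a`, `n_line_b`
#'   and a `tissue` column.
#' @param q_threshold FDR threshold (default 0.05).
#' @param ratio_hi,ratio_lo strict ratio gates (defaults 0.7 / 0.3).
#' @param fdr_scope `"per_tissue"` adjusts within each tissue (each
#'   tissue's tests form one family); `"global"` adjusts across all rows.
#' @return `counts` with `ratio`, `p_value`, `q_value`, `is_ase` appended.
#' @export
call_ase_sites <- function(counts, q_threshold = 0.05, ratio_hi = 0.7,
                           ratio_lo = 0.3,
                           fdr_scope = c("per_tissue", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  out <- data.table::copy(data.table::as.data.table(counts))
  if (!nrow(out)) {
    out[, `:=`(ratio = numeric(), p_value = numeric(), q_value = numeric(),
               is_ase = logical())]
    return(out[])
  }
  out[, ratio := n_line_a / (n_line_a + n_line_b)]
  out[, p_value := binomial_test(n_line_a, n_line_b)]
  if (fdr_scope == "per_tissue" && "tissue" %in% names(out))
    out[, q_value := bh_adjust(p_value), by = tissue]
  else out[, q_value := bh_adjust(p_value)]
  out[, is_ase := q_value < q_threshold &
        (ratio > ratio_hi | ratio < ratio_lo)]
  out[]
}

#' Aggregate site-level ASE calls to genes
#'
#' A site counts as an ASE site when it is significant in at least one
#' individual; a gene is ASE in a tissue when it holds at least
#' `min_ase_sites` such sites supported by at least `min_individuals`
#' distinct individuals.
#'
#' @param calls output of [call_ase_sites()] with a `gene_id` column (or
#'   joinable via `annotations`).
#' @param annotations optional data.table (`chrom`, `pos0`, `gene_id`)
#'   mapping sites to genes (genic categories only); used when `calls`
#'   lacks `gene_id`.
#' @param min_ase_sites,min_individuals gene-call thresholds (defaults 1).
#' @return data.table: gene_id, tissue, n_tested_sites, n_ase_sites,
#'   individuals_supporting, is_ase_gene.
#' @export
aggregate_to_genes <- function(calls, annotations = NULL, min_ase_sites = 1L,
                               min_individuals = 1L) {
  calls <- data.table::as.data.table(calls)
  if (!("gene_id" %in% names(calls))) {
    if (is.null(annotations)) stopf("calls lack gene_id and no annotations given")
    calls <- merge(calls, annotations[, .(chrom, pos0, gene_id)],
                   by = c("chrom", "pos0"))
  }
  calls <- calls[!is.na(gene_id) & gene_id != ""]
  gene <- calls[, {
    site_key <- paste(chrom, pos0)
    ase_sites <- unique(site_key[is_ase])
    .(n_tested_sites = data.table::uniqueN(site_key),
      n_ase_sites = length(ase_sites),
      individuals_supporting = data.table::uniqueN(individual[is_ase]))
  }, by = .(gene_id, tissue)]
  gene[, is_ase_gene := n_ase_sites >= min_ase_sites &
         individuals_supporting >= min_individuals]
  data.table::setorder(gene, tissue, gene_id)
  gene[]
}

#' Exclude known imprinted genes
#'
#' Parent-of-origin monoallelic expression mimics cis-regulatory ASE, so
#' genes on the exclusion list are flagged and removed from the final ASE
#' gene set.  Matching is case-insensitive on the gene symbol; an optional
#' alias table maps alternative symbols to the gene ids in use.
#'
#' @param gene_ase table from [aggregate_to_genes()].
#' @param imprinted character vector of gene symbols (e.g. read from a
#'   one-symbol-per-line file).
#' @param aliases optional named character vector, `alias -> gene_id`.
#' @return `gene_ase` with `imprint_excluded` appended and `is_ase_gene`
#'   forced FALSE on excluded genes; attribute `excluded_genes` lists them.
#' @export
exclude_imprinted <- function(gene_ase, imprinted, aliases = NULL) {
  out <- data.table::copy(data.table::as.data.table(gene_ase))
  imp <- tolower(imprinted)
  if (!is.null(aliases))
    imp <- union(imp, tolower(aliases[tolower(names(aliases)) %in% imp]))
  out[, imprint_excluded := tolower(gene_id) %in% imp]
  excluded <- unique(out$gene_id[out$imprint_excluded & out$is_ase_gene])
  out[imprint_excluded == TRUE, is_ase_gene := FALSE]
  data.table::setattr(out, "excluded_genes", excluded)
  out[]
}

#' Final ASE gene set
#'
#' @param gene_ase table after [exclude_imprinted()].
#' @return sorted character vector of genes ASE in at least one tissue.
#' @export
ase_gene_set <- function(gene_ase)
  sort(unique(gene_ase$gene_id[gene_ase$is_ase_gene]))

#' Tissue specificity and sharing of ASE genes
#'
#' specificity(t) = fraction of tissue t's ASE genes found in no other
#' tissue (NA for tissues with none); also reports the genes ASE in every
#' tissue.
#'
#' @param gene_ase table from [aggregate_to_genes()] /
#'   [exclude_imprinted()].
#' @return list with `per_tissue` (tissue, n_ase_genes, n_specific,
#'   specificity) and `shared_all` (character vector).
#' @export
tissue_overlap_summary <- function(gene_ase) {
  gene_ase <- data.table::as.data.table(gene_ase)
  tissues <- unique(gene_ase$tissue)
  sets <- lapply(tissues, function(t)
    unique(gene_ase$gene_id[gene_ase$tissue == t & gene_ase$is_ase_gene]))
  names(sets) <- tissues
  empty <- data.table::data.table(tissue = character(),
                                  n_ase_genes = integer(),
                                  n_specific = integer(),
                                  specificity = numeric())
  per_tissue <- data.table::rbindlist(c(list(empty), lapply(tissues, function(t) {
    others <- unique(unlist(sets[setdiff(tissues, t)]))
    n <- length(sets[[t]])
    n_spec <- length(setdiff(sets[[t]], others))
    data.table::data.table(tissue = t, n_ase_genes = n, n_specific = n_spec,
                           specificity = if (n) n_spec / n else NA_real_)
  })))
  shared_all <- if (length(sets)) sort(Reduce(intersect, sets)) else character()
  list(per_tissue = per_tissue[], shared_all = shared_all)
}

#' Run the ASE stage end to end from a pooled count table
#'
#' Convenience wrapper: pool replicates, filter depths, test, call sites,
#' aggregate to genes and exclude imprinted genes.
#'
#' @param counts allele-count table (with `replicate` column if
#'   unpooled) carrying `gene_id`.
#' @param imprinted character vector of imprinted gene symbols.
#' @param min_allele_depth,min_total_depth,filter_mode see
#'   [filter_counts()].
#' @param q_threshold,ratio_hi,ratio_lo,fdr_scope see [call_ase_sites()].
#' @param min_ase_sites,min_individuals see [aggregate_to_genes()].
#' @return list: `site_calls`, `gene_ase`, `ase_genes` (final set),
#'   `tissue_overlap`.
#' @export
run_ase_detection <- function(counts, imprinted = character(),
                              min_allele_depth = 20L, min_total_depth = 50L,
                              filter_mode = "literal", q_threshold = 0.05,
                              ratio_hi = 0.7, ratio_lo = 0.3,
                              fdr_scope = "per_tissue", min_ase_sites = 1L,
                              min_individuals = 1L) {
  counts <- data.table::as.data.table(counts)
  if ("replicate" %in% names(counts)) counts <- pool_replicates(counts)
  kept <- filter_counts(counts, min_allele_depth, min_total_depth,
                        filter_mode)
  calls <- call_ase_sites(kept, q_threshold, ratio_hi, ratio_lo, fdr_scope)
  gene_ase <- aggregate_to_genes(calls, min_ase_sites = min_ase_sites,
                                 min_individuals = min_individuals)
  gene_ase <- exclude_imprinted(gene_ase, imprinted)
  list(site_calls = calls, gene_ase = gene_ase,
       ase_genes = ase_gene_set(gene_ase),
       tissue_overlap = tissue_overlap_summary(gene_ase))
}
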