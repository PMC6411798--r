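# Breed-discriminating SNPs: sites where the two parental lines carry
# distinguishable alleles, so each F1 allele's line of origin is known.

#' Filter sites by Phred-scaled site quality
#'
#' Sites with `QUAL < min_qual` are removed (a site at exactly `min_qual`
#' is kept).
#'
#' @param vs a [variant_sites()] object.
#' @param min_qual quality threshold (default 30).
#' @return a filtered [variant_sites()]; attribute `n_filtered` counts the
#'   removed sites.
#' @export
filter_by_qual <- function(vs, min_qual = 30) {
  keep <- !is.na(vs$sites$qual) & vs$sites$qual >= min_qual
  out <- subset_sites(vs, keep)
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Identify breed-discriminating SNPs
#'
#' In `strict` mode (the default) a site discriminates the lines when every
#' non-missing line-A parent is homozygous for one allele, every non-missing
#' line-B parent is homozygous for the other, and the missing fraction per
#' line is at most `max_missing_frac`.  In `frequency` mode a site
#' discriminates when the absolute alternate-allele frequency difference
#' between the lines is at least `min_freq_diff`; each line's majority
#' allele is recorded.  Strict mode guarantees that every F1 is
#' heterozygous and that the allelic line of origin is unambiguous, which
#' the ASE stage requires.
#'
#' @param vs a [variant_sites()] with YUNLING- and NUBIAN-labelled samples.
#' @param mode `"strict"` or `"frequency"`.
#' @param max_missing_frac maximum per-line fraction of missing genotypes
#'   (strict mode).
#' @param min_freq_diff minimum allele-frequency difference (frequency
#'   mode).
#' @return data.table with columns chrom, pos0, ref, alt, qual, allele_a,
#'   allele_b, n_missing_a, n_missing_b; attribute `n_skipped_unscorable`
#'   tallies sites where a line had zero genotyped samples.
#' @export
assign_discriminating_snps <- function(vs, mode = c("strict", "frequency"),
                                       max_missing_frac = 0,
                                       min_freq_diff = 0.8) {
  mode <- match.arg(mode)
  a_cols <- vs$samples$population == "YUNLING"
  b_cols <- vs$samples$population == "NUBIAN"
  if (!any(a_cols) || !any(b_cols))
    stopf("need samples labelled YUNLING and NUBIAN")
  ga <- vs$geno[, a_cols, drop = FALSE]
  gb <- vs$geno[, b_cols, drop = FALSE]
  n_miss_a <- rowSums(is.na(ga))
  n_miss_b <- rowSums(is.na(gb))
  n_ok_a <- ncol(ga) - n_miss_a
  n_ok_b <- ncol(gb) - n_miss_b
  unscorable <- n_ok_a == 0L | n_ok_b == 0L

  if (mode == "strict") {
    sum_a <- rowSums(ga, na.rm = TRUE)
    sum_b <- rowSums(gb, na.rm = TRUE)
    hom_ref_a <- sum_a == 0L
    hom_alt_a <- sum_a == 2L * n_ok_a
    hom_ref_b <- sum_b == 0L
    hom_alt_b <- sum_b == 2L * n_ok_b
    # rowSums says nothing about per-sample homozygosity unless all 0 or all 2
    all_hom_a <- apply(ga, 1L, function(g) all(g[!is.na(g)] %in% c(0L, 2L)))
    all_hom_b <- apply(gb, 1L, function(g) all(g[!is.na(g)] %in% c(0L, 2L)))
    disc <- !unscorable & all_hom_a & all_hom_b &
      ((hom_ref_a & hom_alt_b) | (hom_alt_a & hom_ref_b)) &
      n_miss_a / ncol(ga) <= max_missing_frac &
      n_miss_b / ncol(gb) <= max_missing_frac
    allele_a <- ifelse(hom_ref_a, vs$sites$ref, vs$sites$alt)
    allele_b <- ifelse(hom_ref_a, vs$sites$alt, vs$sites$ref)
  } else {
    freq_a <- rowSums(ga, na.rm = TRUE) / (2L * pmax(n_ok_a, 1L))
    freq_b <- rowSums(gb, na.rm = TRUE) / (2L * pmax(n_ok_b, 1L))
    disc <- !unscorable & abs(freq_a - freq_b) >= min_freq_diff
    allele_a <- ifelse(freq_a >= 0.5, vs$sites$alt, vs$sites$ref)
    allele_b <- ifelse(freq_b >= 0.5, vs$sites$alt, vs$sites$ref)
  }
  out <- data.table::data.table(
    chrom = vs$sites$chrom, pos0 = vs$sites$pos0, ref = vs$sites$ref,
    alt = vs$sites$alt, qual = vs$sites$qual,
    allele_a = allele_a, allele_b = allele_b,
    n_missing_a = n_miss_a, n_missing_b = n_miss_b)[disc]
  data.table::setattr(out, "n_skipped_unscorable", sum(unscorable))
  out[]
}

SNP_CATEGORIES <- c("exonic", "splice_region", "intronic", "upstream",
                    "downstream", "intergenic")

#' Annotate SNPs against gene models
#'
#' Category precedence: exonic > splice_region > intronic >
#' upstream/downstream > intergenic.  A splice-region SNP is an intronic
#' position within `splice_bp` of an exon boundary; upstream/downstream are
#' strand-aware windows of `upstream_downstream_bp` around the gene span
#' (1 kb and 2 bp defaults follow common annotator practice).  A SNP
#' overlapping several genes receives one row per gene; the per-SNP summary
#' category is resolved by precedence (see [annotation_category_summary()]).
#'
#' @param snps data.table with `chrom`, `pos0` (plus any other columns,
#'   e.g. a discriminating-SNP table).
#' @param gm a [gene_models()] object.
#' @param upstream_downstream_bp flank width for upstream/downstream.
#' @param splice_bp intronic distance from an exon boundary that counts as
#'   splice region.
#' @return list with `per_snp` (input columns + `category`, `gene_id`; one
#'   row per SNP, best category) and `per_gene` (snp/gene pairs for every
#'   overlapped gene with the category relative to that gene).
#' @export
annotate_snps <- function(snps, gm, upstream_downstream_bp = 1000L,
                          splice_bp = 2L) {
  snps <- data.table::as.data.table(snps)
  hits <- vector("list", nrow(gm$genes))
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i]
    lo <- g$start - upstream_downstream_bp
    hi <- g$end + upstream_downstream_bp
    idx <- which(snps$chrom == g$chrom & snps$pos0 >= lo & snps$pos0 < hi)
    if (!length(idx)) next
    p <- snps$pos0[idx]
    ex <- gm$exons[gene_id == g$gene_id]
    in_gene <- p >= g$start & p < g$end
    in_exon <- rep(FALSE, length(p))
    near_exon <- rep(FALSE, length(p))
    for (k in seq_len(nrow(ex))) {
      in_exon <- in_exon | (p >= ex$start[k] & p < ex$end[k])
      near_exon <- near_exon |
        (p >= ex$start[k] - splice_bp & p < ex$start[k]) |
        (p >= ex$end[k] & p < ex$end[k] + splice_bp)
    }
    five_prime <- if (g$strand == "+") p < g$start else p >= g$end
    cat_i <- ifelse(in_gene & in_exon, "exonic",
             ifelse(in_gene & near_exon, "splice_region",
             ifelse(in_gene, "intronic",
             ifelse(five_prime, "upstream", "downstream"))))
    hits[[i]] <- data.table::data.table(snp = idx, gene_id = g$gene_id,
                                        category = cat_i)
  }
  per_gene <- data.table::rbindlist(hits)
  if (!nrow(per_gene))
    per_gene <- data.table::data.table(snp = integer(), gene_id = character(),
                                       category = character())
  # per-SNP best category by precedence
  prec <- match(per_gene$category, SNP_CATEGORIES)
  best <- rep(NA_integer_, nrow(snps))
  best_gene <- rep("", nrow(snps))
  if (nrow(per_gene)) {
    o <- order(per_gene$snp, prec)
    pg <- per_gene[o]
    first <- !duplicated(pg$snp)
    best[pg$snp[first]] <- match(pg$category[first], SNP_CATEGORIES)
    gene_rel <- pg$category[first] %in% c("exonic", "splice_region", "intronic")
    best_gene[pg$snp[first]] <- ifelse(gene_rel, pg$gene_id[first], "")
  }
  per_snp <- data.table::copy(snps)
  per_snp[, category := ifelse(is.na(best), "intergenic",
                               SNP_CATEGORIES[best])]
  per_snp[, gene_id := best_gene]
  list(per_snp = per_snp[], per_gene = per_gene[order(snp)])
}

#' Classify a coding change
#'
#' Substitutes the alternate base into the coding-strand codon and
#' translates both with the standard genetic code.
#'
#' @param codon three-letter coding-strand reference codon.
#' @param pos position of the substituted base within the codon (1-3).
#' @param alt alternate base on the coding strand.
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"stopgain"`,
#'   `"stoploss"`.
#' @export
classify_coding_change <- function(codon, pos, alt) {
  stopifnot(nchar(codon) == 3L, pos %in% 1:3, alt %in% DNA_BASES)
  gc <- Biostrings::GENETIC_CODE
  alt_codon <- codon
  substr(alt_codon, pos, pos) <- alt
  aa_ref <- unname(gc[codon])
  aa_alt <- unname(gc[alt_codon])
  if (is.na(aa_ref) || is.na(aa_alt)) stopf("invalid codon %s/%s", codon, alt_codon)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "stopgain"
  else if (aa_ref == "*") "stoploss"
  else "nonsynonymous"
}

#' Classify the coding change of a genomic SNP within a gene
#'
#' Locates the SNP in the gene's CDS, rebuilds the codon on the coding
#' strand from a reference genome (reverse-complementing for minus-strand
#' genes) and delegates to [classify_coding_change()].
#'
#' @param chrom,pos0 SNP position (0-based).
#' @param ref,alt SNP alleles on the forward genomic strand.
#' @param gm a [gene_models()] object.
#' @param gene_id gene to classify against.
#' @param genome named character vector/list of chromosome sequences.
#' @return a coding-change class, or `"none"` when the SNP is exonic but
#'   outside the CDS (UTR).
#' @export
coding_change_for_site <- function(chrom, pos0, ref, alt, gm, gene_id,
                                   genome) {
  gid <- gene_id
  g <- gm$genes[gene_id == gid]
  if (!nrow(g)) stopf("unknown gene %s", gid)
  cds <- gm$cds[gene_id == gid][order(start)]
  if (!nrow(cds)) return("none")
  in_cds <- pos0 >= cds$start & pos0 < cds$end
  if (!any(in_cds)) return("none")
  seq_chr <- toupper(as.character(genome[[chrom]]))
  # CDS position in transcription order
  if (g$strand == "+") {
    before <- sum(pmax(0L, pmin(pos0, cds$end) - cds$start))
    cds_pos <- before  # 0-based offset into spliced CDS
  } else {
    after <- sum(pmax(0L, cds$end - pmax(pos0 + 1L, cds$start)))
    cds_pos <- after
  }
  spliced <- paste(substring(seq_chr, cds$start + 1L, cds$end),
                   collapse = "")
  if (g$strand == "-") spliced <- revcomp(spliced)
  codon_i <- cds_pos %/% 3L
  within <- cds_pos %% 3L
  codon <- substr(spliced, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return("none")  # trailing partial codon
  alt_cs <- if (g$strand == "+") alt else complement_base(alt)
  ref_cs <- if (g$strand == "+") ref else complement_base(ref)
  if (substr(codon, within + 1L, within + 1L) != ref_cs)
    stopf("reference base mismatch at %s:%d in %s", chrom, pos0 + 1L, gene_id)
  classify_coding_change(codon, within + 1L, alt_cs)
}

#' Transition/transversion summary
#'
#' Transitions are A<->G and C<->T.
#'
#' @param snps data.table with `ref` and `alt` columns.
#' @return list with `n_ts`, `n_tv` and `ratio` (`NA` when `n_tv` is 0).
#' @export
transition_transversion_summary <- function(snps) {
  purine <- c("A", "G")
  is_ts <- (snps$ref %in% purine) == (snps$alt %in% purine)
  n_ts <- sum(is_ts)
  n_tv <- sum(!is_ts)
  list(n_ts = n_ts, n_tv = n_tv,
       ratio = if (n_tv == 0L) NA_real_ else n_ts / n_tv)
}

#' Count discriminating SNPs per gene
#'
#' Every SNP annotated to a gene (exonic, intronic or splice region) is
#' counted for that gene; a SNP overlapping two genes counts for both.
#'
#' @param annotation result of [annotate_snps()].
#' @return data.table `gene_id`, `n_snps` (genes with zero SNPs absent).
#' @export
per_gene_snp_counts <- function(annotation) {
  pg <- annotation$per_gene[category %in% c("exonic", "intronic",
                                            "splice_region")]
  if (!nrow(pg)) return(data.table::data.table(gene_id = character(),
                                               n_snps = integer()))
  pg[, .(n_snps = .N), by = gene_id][order(gene_id)]
}

#' Tally annotation categories
#'
#' The report schema mirrors the usual annotator summary rows: every SNP
#' contributes exactly one category, so the tallies sum to the input size.
#'
#' @param annotation result of [annotate_snps()].
#' @return data.table `category`, `n` over all six categories.
#' @export
annotation_category_summary <- function(annotation) {
  n <- table(factor(annotation$per_snp$category, SNP_CATEGORIES))
  data.table::data.table(category = SNP_CATEGORIES, n = as.integer(n))
}
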