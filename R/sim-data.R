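# Truth-labelled synthetic dataset generator.
#
# The generated world: two parental populations whose allele frequencies at
# neutral sites are independent Beta(0.5, 0.5) draws; inside planted sweep
# windows the swept population draws Beta(40, 1) (near fixation -> low Hp)
# and the other Beta(1, 40) (-> high Fst).  Each gene carries a handful of
# strict fixed-difference SNPs in its exons, so every F1 is heterozygous
# there and allele counts can be assigned a parental line of origin.  RNA
# allele counts are beta-binomial around the gene's true line-A ratio theta
# (0.5 for neutral genes).

rbetabinom <- function(n, size, theta, rho) {
  # beta-binomial via beta-mixed binomial; rho = 0 degenerates to binomial
  if (rho == 0) return(stats::rbinom(n, size, theta))
  a <- theta * (1 - rho) / rho
  b <- (1 - theta) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

parent_sample_names <- function(cfg)
  c(sprintf("A%d", seq_len(cfg$n_parents_a)),
    sprintf("B%d", seq_len(cfg$n_parents_b)))

parent_population_map <- function(cfg)
  stats::setNames(rep(c("YUNLING", "NUBIAN"),
                      c(cfg$n_parents_a, cfg$n_parents_b)),
                  parent_sample_names(cfg))

f1_population_map <- function(cfg)
  stats::setNames(rep("F1", cfg$n_f1), sprintf("F1_%d", seq_len(cfg$n_f1)))

random_alt <- function(ref, ts_prob = 0.694) {
  # alt base: transition with probability ts_prob, else one of the two
  # transversions -- gives the generated genome a realistic Ts/Tv ratio
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- stats::runif(length(ref)) < ts_prob
  tv_pick <- stats::runif(length(ref)) < 0.5
  tv <- ifelse(ref %in% c("A", "G"),
               ifelse(tv_pick, "C", "T"),
               ifelse(tv_pick, "A", "G"))
  ifelse(is_ts, unname(transition[ref]), tv)
}

#' Simulate parental genotypes and the site truth table
#'
#' Background sites are placed uniformly per chromosome; each gene
#' additionally contributes `n_snps_per_gene` strict fixed-difference sites
#' (line A homozygous reference, line B homozygous alternate) inside its
#' exons.  Diploid genotypes are binomial draws from the population
#' frequency.  Deterministic given the config.
#'
#' @param cfg a [sim_config()].
#' @return list with `vcf` (a [variant_sites()] of all parents),
#'   `truth_sites` (data.table: chrom, pos0, ref, alt, freq_a, freq_b,
#'   in_sweep, gene_id) and `gene_models`.
#' @export
simulate_parent_genomes <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "parents"))
  gm <- sim_gene_layout(cfg)

  # genic fixed-difference sites at deterministic exon offsets
  offs <- GENE_SNP_OFFSETS[seq_len(cfg$n_snps_per_gene)]
  genic <- gm$genes[, .(pos0 = start + offs), by = .(gene_id, chrom)]

  per_chrom <- table(factor(rep(cfg$chrom_names,
                                length.out = cfg$n_sites),
                            cfg$chrom_names))
  bg <- data.table::rbindlist(lapply(cfg$chrom_names, function(ch) {
    data.table::data.table(
      gene_id = NA_character_, chrom = ch,
      pos0 = sort(sample.int(cfg$chrom_len, per_chrom[[ch]])) - 1L)
  }))
  sites <- data.table::rbindlist(list(genic, bg), use.names = TRUE)
  sites <- sites[!duplicated(paste(chrom, pos0))]
  data.table::setorder(sites, chrom, pos0)

  n <- nrow(sites)
  sites[, ref := sample(DNA_BASES, n, replace = TRUE)]
  sites[, alt := random_alt(ref)]

  # population allele frequencies
  sites[, `:=`(freq_a = stats::rbeta(n, 0.5, 0.5),
               freq_b = stats::rbeta(n, 0.5, 0.5),
               in_sweep = FALSE, sweep_target = NA_character_)]
  sw <- cfg$sweep_windows
  for (i in seq_len(nrow(sw))) {
    idx <- sites$chrom == sw$chrom[i] & sites$pos0 >= sw$start[i] &
      sites$pos0 < sw$end[i]
    k <- sum(idx)
    if (!k) next
    hi <- stats::rbeta(k, 40, 1)
    lo <- stats::rbeta(k, 1, 40)
    if (sw$target[i] == "A") {
      sites[idx, `:=`(freq_a = hi, freq_b = lo)]
    } else {
      sites[idx, `:=`(freq_a = lo, freq_b = hi)]
    }
    sites[idx, `:=`(in_sweep = TRUE, sweep_target = sw$target[i])]
  }
  # genic truth sites: strict fixed difference, line A = ref
  sites[!is.na(gene_id), `:=`(freq_a = 0, freq_b = 1)]

  qual <- pmax(31, round(stats::rnorm(n, cfg$qual_mean, 40), 1))
  low <- is.na(sites$gene_id) & stats::runif(n) < cfg$qual_low_frac
  qual[low] <- round(stats::runif(sum(low), 5, 29.9), 1)

  n_a <- cfg$n_parents_a; n_b <- cfg$n_parents_b
  geno <- cbind(
    matrix(stats::rbinom(n * n_a, 2L, rep(sites$freq_a, n_a)), n, n_a),
    matrix(stats::rbinom(n * n_b, 2L, rep(sites$freq_b, n_b)), n, n_b))
  colnames(geno) <- parent_sample_names(cfg)

  vs <- variant_sites(
    data.table::data.table(chrom = sites$chrom, pos0 = sites$pos0,
                           ref = sites$ref, alt = sites$alt, qual = qual),
    geno,
    data.table::data.table(sample = parent_sample_names(cfg),
                           population = unname(parent_population_map(cfg))))
  list(vcf = vs, truth_sites = sites[], gene_models = gm)
}

#' Simulate F1 genotypes by Mendelian draws from the parents
#'
#' Each F1 receives, at every site, one allele drawn from a random
#' haplotype of its line-A dam and one from its line-B sire (parents
#' assigned cyclically).  At strict fixed-difference sites every F1 is
#' therefore heterozygous.
#'
#' @param parents a [variant_sites()] of the parental panel.
#' @param cfg a [sim_config()].
#' @return a [variant_sites()] of the F1 individuals (QUAL copied from the
#'   parental sites).
#' @export
simulate_f1 <- function(parents, cfg) {
  set.seed(derive_seed(cfg$seed, "f1"))
  n <- nrow(parents$sites)
  a_cols <- which(parents$samples$population == "YUNLING")
  b_cols <- which(parents$samples$population == "NUBIAN")
  dams <- a_cols[((seq_len(cfg$n_f1) - 1L) %% length(a_cols)) + 1L]
  sires <- b_cols[((seq_len(cfg$n_f1) - 1L) %% length(b_cols)) + 1L]
  geno <- matrix(NA_integer_, n, cfg$n_f1)
  for (j in seq_len(cfg$n_f1)) {
    pa <- parents$geno[, dams[j]]
    pb <- parents$geno[, sires[j]]
    # transmitted allele is Bernoulli(dosage / 2)
    geno[, j] <- stats::rbinom(n, 1L, pa / 2) + stats::rbinom(n, 1L, pb / 2)
  }
  colnames(geno) <- names(f1_population_map(cfg))
  variant_sites(parents$sites, geno,
                data.table::data.table(sample = names(f1_population_map(cfg)),
                                       population = "F1"))
}

gene_truth_table <- function(cfg, gm) {
  g <- data.table::data.table(gene_id = gm$genes$gene_id)
  g[, `:=`(is_ase = gene_id %in% cfg$ase_genes$gene_id,
           is_imprinted = gene_id %in% cfg$imprinted_genes$gene_id,
           theta = 0.5)]
  if (nrow(cfg$ase_genes))
    g[cfg$ase_genes, theta := i.theta, on = "gene_id"]
  if (nrow(cfg$imprinted_genes))
    g[cfg$imprinted_genes, theta := i.theta, on = "gene_id"]
  g[]
}

#' Simulate RNA allele counts at F1-heterozygous genic sites
#'
#' For every genic truth site, F1 individual heterozygous there, tissue and
#' replicate: total depth ~ Poisson(`depth_mean`) and line-A count ~
#' BetaBinomial(depth, theta_gene, rho).  Line A carries the reference
#' allele at every planted site, so `n_ref = n_line_a`.
#'
#' @param f1 the F1 [variant_sites()].
#' @param truth_sites site truth table from [simulate_parent_genomes()].
#' @param cfg a [sim_config()].
#' @return data.table with columns chrom, pos0, ref, alt, gene_id,
#'   individual, tissue, replicate, n_ref, n_alt, n_other, n_line_a,
#'   n_line_b.
#' @export
simulate_allele_counts <- function(f1, truth_sites, cfg) {
  set.seed(derive_seed(cfg$seed, "counts"))
  gtruth <- gene_truth_table(cfg, sim_gene_layout(cfg))
  genic <- truth_sites[!is.na(gene_id)]
  genic <- merge(genic, gtruth[, .(gene_id, theta)], by = "gene_id",
                 sort = FALSE)
  key <- paste(f1$sites$chrom, f1$sites$pos0)
  row_of <- match(paste(genic$chrom, genic$pos0), key)

  grid <- data.table::CJ(site = seq_len(nrow(genic)),
                         individual = f1$samples$sample,
                         tissue = cfg$tissues,
                         replicate = seq_len(cfg$replicates_per_tissue),
                         sorted = FALSE)
  het <- f1$geno[row_of[grid$site], , drop = FALSE][
    cbind(seq_len(nrow(grid)), match(grid$individual, f1$samples$sample))] == 1L
  grid <- grid[het & !is.na(het)]

  depth <- stats::rpois(nrow(grid), cfg$depth_mean)
  n_a <- rbetabinom(nrow(grid), depth, genic$theta[grid$site],
                    cfg$overdispersion)
  out <- data.table::data.table(
    chrom = genic$chrom[grid$site], pos0 = genic$pos0[grid$site],
    ref = genic$ref[grid$site], alt = genic$alt[grid$site],
    gene_id = genic$gene_id[grid$site],
    individual = grid$individual, tissue = grid$tissue,
    replicate = grid$replicate,
    n_ref = n_a, n_alt = depth - n_a, n_other = 0L,
    n_line_a = n_a, n_line_b = depth - n_a)
  data.table::setorder(out, chrom, pos0, individual, tissue, replicate)
  out[]
}

#' Render simulated allele counts as synthetic SAM reads
#'
#' Emits 100-bp single-end reads (CIGAR `100M`, MAPQ 60, base quality 30)
#' whose base at the SNP offset realises the drawn ref/alt counts, one read
#' list per count row.  Planted sites are >= 150 bp apart, so no read
#' covers two sites and the allele counter recovers the planted counts
#' exactly.
#'
#' @param counts rows of the table from [simulate_allele_counts()] (one
#'   alignment unit, e.g. one individual/tissue/replicate).
#' @return a read data.table in the layout of [read_sam()].
#' @export
counts_to_sam_reads <- function(counts) {
  counts <- data.table::as.data.table(counts)
  rows <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    n_ref <- counts$n_ref[i]; n_alt <- counts$n_alt[i]
    total <- n_ref + n_alt
    if (!total) { rows[[i]] <- NULL; next }
    start <- max(0L, counts$pos0[i] - 49L)
    off <- counts$pos0[i] - start
    base_tpl <- strrep("A", 100L)
    mk <- function(allele) {
      s <- base_tpl
      substr(s, off + 1L, off + 1L) <- allele
      s
    }
    rows[[i]] <- data.table::data.table(
      qname = sprintf("r_%s_%d_%s_%s_%d_%d", counts$chrom[i], counts$pos0[i],
                      counts$individual[i], counts$tissue[i],
                      counts$replicate[i], seq_len(total)),
      flag = 0L, chrom = counts$chrom[i], pos0 = start, mapq = 60L,
      cigar = "100M",
      seq = c(rep(mk(counts$ref[i]), n_ref), rep(mk(counts$alt[i]), n_alt)),
      qual = strrep("?", 100L))  # '?' is Phred 30
  }
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) return(out)
  data.table::setorder(out, chrom, pos0, qname)
  out[]
}

#' Simulate a gene x sample FPKM table
#'
#' Log-normal expression; genes with planted ASE are drawn with a higher
#' location parameter (the generated world assumes imbalanced genes sit
#' among the better-expressed genes, which is what makes them detectable),
#' and pseudogenes are near-silent.
#'
#' @param cfg a [sim_config()].
#' @return data.table: gene_id, sample (tissue_individual), fpkm.
#' @export
simulate_fpkm <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "fpkm"))
  gm <- sim_gene_layout(cfg)
  gtruth <- gene_truth_table(cfg, gm)
  samples <- data.table::CJ(tissue = cfg$tissues,
                            individual = names(f1_population_map(cfg)))
  grid <- data.table::CJ(gene_id = gm$genes$gene_id,
                         sample = paste(samples$tissue, samples$individual,
                                        sep = "_"))
  grid <- merge(grid, gtruth[, .(gene_id, is_ase)], by = "gene_id")
  grid <- merge(grid, gm$genes[, .(gene_id, biotype)], by = "gene_id")
  meanlog <- ifelse(grid$is_ase, 2, 1)
  grid[, fpkm := round(stats::rlnorm(.N, meanlog, 1), 4)]
  grid[biotype == "pseudogene",
       fpkm := round(stats::runif(.N, 0, 0.009), 4)]
  grid[, c("is_ase", "biotype") := NULL]
  data.table::setorder(grid, gene_id, sample)
  grid[]
}

window_truth_table <- function(cfg, window = 150000L, step = 75000L) {
  w <- make_windows(stats::setNames(rep(cfg$chrom_len, cfg$n_chrom),
                                    cfg$chrom_names), window, step)
  w[, `:=`(is_sweep = FALSE, sweep_target = NA_character_)]
  sw <- cfg$sweep_windows
  for (i in seq_len(nrow(sw)))
    w[chrom == sw$chrom[i] & start == sw$start[i] & end == sw$end[i],
      `:=`(is_sweep = TRUE, sweep_target = sw$target[i])]
  w[]
}

#' Simulate the complete dataset in memory
#'
#' @param cfg a [sim_config()].
#' @return list with elements `parents`, `f1` (variant_sites),
#'   `gene_models`, `counts`, `fpkm`, `imprinted` (character vector of gene
#'   ids), and `truth` (list: sites, genes, windows).
#' @export
simulate_dataset <- function(cfg) {
  pg <- simulate_parent_genomes(cfg)
  f1 <- simulate_f1(pg$vcf, cfg)
  counts <- simulate_allele_counts(f1, pg$truth_sites, cfg)
  fpkm <- simulate_fpkm(cfg)
  list(parents = pg$vcf, f1 = f1, gene_models = pg$gene_models,
       counts = counts, fpkm = fpkm,
       imprinted = cfg$imprinted_genes$gene_id,
       truth = list(sites = pg$truth_sites,
                    genes = gene_truth_table(cfg, pg$gene_models),
                    windows = window_truth_table(cfg)))
}

#' Write the complete synthetic dataset to a directory
#'
#' Writes `parents.vcf`, `f1.vcf`, `counts.tsv`, `genes.gff3`,
#' `imprinted.txt`, `fpkm.tsv`, `truth/{sites,genes,windows}.tsv` and a
#' `manifest.tsv` listing every file with its row count.  With
#' `sam = TRUE`, additionally writes one SAM per (tissue, individual,
#' replicate) under `sam/`.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param sam also emit synthetic RNA alignments as SAM.
#' @return the manifest data.table, invisibly the dataset list as attribute
#'   `"dataset"`.
#' @export
write_dataset <- function(cfg, outdir, sam = FALSE) {
  ds <- simulate_dataset(cfg)
  dir.create(file.path(outdir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  counts_out <- data.table::copy(ds$counts)[, pos := pos0 + 1L][, pos0 := NULL]
  data.table::setcolorder(counts_out, "pos", after = "chrom")
  files <- list(
    `parents.vcf` = {write_vcf(ds$parents, file.path(outdir, "parents.vcf"))
      nrow(ds$parents$sites)},
    `f1.vcf` = {write_vcf(ds$f1, file.path(outdir, "f1.vcf"))
      nrow(ds$f1$sites)},
    `counts.tsv` = {write_tsv(counts_out, file.path(outdir, "counts.tsv"))
      nrow(counts_out)},
    `genes.gff3` = {write_gff3(ds$gene_models, file.path(outdir, "genes.gff3"))
      nrow(ds$gene_models$genes)},
    `imprinted.txt` = {writeLines(ds$imprinted,
                                  file.path(outdir, "imprinted.txt"))
      length(ds$imprinted)},
    `fpkm.tsv` = {write_tsv(ds$fpkm, file.path(outdir, "fpkm.tsv"))
      nrow(ds$fpkm)},
    `truth/sites.tsv` = {write_tsv(ds$truth$sites,
                                   file.path(outdir, "truth", "sites.tsv"))
      nrow(ds$truth$sites)},
    `truth/genes.tsv` = {write_tsv(ds$truth$genes,
                                   file.path(outdir, "truth", "genes.tsv"))
      nrow(ds$truth$genes)},
    `truth/windows.tsv` = {write_tsv(ds$truth$windows,
                                     file.path(outdir, "truth", "windows.tsv"))
      nrow(ds$truth$windows)})
  if (sam) {
    dir.create(file.path(outdir, "sam"), showWarnings = FALSE)
    seqinfo <- stats::setNames(rep(cfg$chrom_len, cfg$n_chrom),
                               cfg$chrom_names)
    units <- unique(ds$counts[, .(tissue, individual, replicate)])
    for (i in seq_len(nrow(units))) {
      u <- units[i]
      reads <- counts_to_sam_reads(ds$counts[u, on = names(u)])
      fn <- sprintf("sam/%s_%s_rep%d.sam", u$tissue, u$individual,
                    u$replicate)
      write_sam(reads, file.path(outdir, fn), seqinfo)
      files[[fn]] <- nrow(reads)
    }
  }
  manifest <- data.table::data.table(file = names(files),
                                     n_rows = unlist(files))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  data.table::setattr(manifest, "dataset", ds)
  invisible(manifest[])
}
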