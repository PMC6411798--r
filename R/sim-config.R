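# Simulation configuration.  The defaults restate the study design the
# pipeline is meant for -- two divergent parental breeds (6 dams of line A,
# 4 sires of line B), nine F1 hybrids, six tissues with two technical
# replicates each -- on a deliberately small two-chromosome genome so the
# full pipeline runs in seconds.

#' Build a simulation configuration
#'
#' @param seed integer RNG seed; every output of the generator is a pure
#'   function of the configuration including this seed.
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (all chromosomes equal).
#' @param n_parents_a,n_parents_b diploid parents sequenced per line
#'   (defaults 6 and 4, the dam/sire panel of the emulated design).
#' @param n_f1 F1 hybrid individuals (default 9).
#' @param n_sites background SNP sites across the genome (uniformly placed;
#'   genic truth sites are added on top).
#' @param n_snps_per_gene fixed-difference SNPs planted inside each gene's
#'   exons (2--9); these are the informative ASE sites.
#' @param sweep_windows data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `target` (`"A"` or `"B"`): windows where the
#'   target population's alternate-allele frequency is drawn from
#'   Beta(40, 1) (near fixation, low heterozygosity) and the other
#'   population's from Beta(1, 40), producing the joint high-Fst / low-Hp
#'   sweep signature.  `NULL` selects two default windows, each aligned to
#'   the 75-kb scan grid and containing one gene.
#' @param n_genes number of genes, tiled evenly across chromosomes.
#' @param ase_genes data.frame with columns `gene_id`, `theta`: genes with
#'   planted allelic imbalance, `theta` = expected fraction of RNA reads
#'   carrying the line-A allele.  `NULL` selects defaults (the two
#'   sweep-window genes plus six genes far from any sweep, theta 0.8/0.2).
#' @param imprinted_genes data.frame with columns `gene_id`, `theta`
#'   (near 0 or near 1): genes with planted parent-of-origin monoallelic
#'   expression, also written to the imprinted exclusion list.
#' @param depth_mean expected RNA read depth per site, individual, tissue
#'   and replicate (Poisson).
#' @param overdispersion beta-binomial intra-class correlation rho in
#'   [0, 1); 0 gives a pure binomial.  Default 0.01, mild technical
#'   overdispersion.
#' @param qual_mean,qual_low_frac site QUAL is Normal(qual_mean, 40)
#'   truncated at 31, except a `qual_low_frac` fraction of background sites
#'   that draw QUAL ~ Uniform(5, 29.9) and should fall to the quality
#'   filter.
#' @param tissues character vector of tissue names.
#' @param replicates_per_tissue technical replicates per tissue sample.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 12e6,
                       n_parents_a = 6L,
                       n_parents_b = 4L,
                       n_f1 = 9L,
                       n_sites = 4000L,
                       n_snps_per_gene = 4L,
                       sweep_windows = NULL,
                       n_genes = 60L,
                       ase_genes = NULL,
                       imprinted_genes = NULL,
                       depth_mean = 80,
                       overdispersion = 0.01,
                       qual_mean = 220,
                       qual_low_frac = 0.05,
                       tissues = c("liver", "bone", "muscle", "fat",
                                   "skin", "mammary"),
                       replicates_per_tissue = 2L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = as.integer(chrom_len),
              n_parents_a = as.integer(n_parents_a),
              n_parents_b = as.integer(n_parents_b),
              n_f1 = as.integer(n_f1), n_sites = as.integer(n_sites),
              n_snps_per_gene = as.integer(n_snps_per_gene),
              sweep_windows = sweep_windows, n_genes = as.integer(n_genes),
              ase_genes = ase_genes, imprinted_genes = imprinted_genes,
              depth_mean = depth_mean, overdispersion = overdispersion,
              qual_mean = qual_mean, qual_low_frac = qual_low_frac,
              tissues = tissues,
              replicates_per_tissue = as.integer(replicates_per_tissue))
  class(cfg) <- "sim_config"
  cfg$chrom_names <- paste0("chr", seq_len(cfg$n_chrom))
  gm <- sim_gene_layout(cfg)
  if (is.null(cfg$sweep_windows)) cfg$sweep_windows <- default_sweep_windows(cfg, gm)
  cfg$sweep_windows <- data.table::as.data.table(cfg$sweep_windows)
  if (is.null(cfg$ase_genes)) cfg$ase_genes <- default_ase_genes(cfg, gm)
  cfg$ase_genes <- data.table::as.data.table(cfg$ase_genes)
  if (is.null(cfg$imprinted_genes))
    cfg$imprinted_genes <- default_imprinted_genes(cfg, gm)
  cfg$imprinted_genes <- data.table::as.data.table(cfg$imprinted_genes)
  validate_sim_config(cfg, gm)
  cfg
}

validate_sim_config <- function(cfg, gm = sim_gene_layout(cfg)) {
  for (f in c("n_chrom", "chrom_len", "n_parents_a", "n_parents_b", "n_f1",
              "n_sites", "n_genes", "replicates_per_tissue"))
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1L) stopf("%s must be a count >= 1", f)
  if (cfg$n_parents_a < 2L || cfg$n_parents_b < 2L)
    stopf("need >= 2 parents per line for Fst components")
  if (!(cfg$n_snps_per_gene %in% 2:9))
    stopf("n_snps_per_gene must be in 2..9")
  if (cfg$overdispersion < 0 || cfg$overdispersion >= 1)
    stopf("overdispersion rho must be in [0, 1)")
  if (!length(cfg$tissues)) stopf("need at least one tissue")
  sw <- cfg$sweep_windows
  if (nrow(sw)) {
    if (!all(c("chrom", "start", "end", "target") %in% names(sw)))
      stopf("sweep_windows needs chrom/start/end/target")
    if (!all(sw$target %in% c("A", "B"))) stopf("sweep target must be A or B")
    if (!all(sw$chrom %in% cfg$chrom_names) || any(sw$start < 0) ||
        any(sw$end > cfg$chrom_len) || any(sw$start >= sw$end))
      stopf("sweep window outside chromosome bounds")
  }
  for (nm in c("ase_genes", "imprinted_genes")) {
    tab <- cfg[[nm]]
    if (nrow(tab)) {
      if (any(tab$theta <= 0 | tab$theta >= 1))
        stopf("%s theta must lie strictly inside (0, 1)", nm)
      bad <- setdiff(tab$gene_id, gm$genes$gene_id)
      if (length(bad)) stopf("%s names unknown gene: %s", nm, bad[1])
    }
  }
  both <- intersect(cfg$ase_genes$gene_id, cfg$imprinted_genes$gene_id)
  if (length(both)) stopf("gene in both ase_genes and imprinted_genes: %s", both[1])
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d: %d x %.1f Mb chrom, %d+%d parents,",
                     " %d F1, %d bg sites, %d genes, %d sweep window(s),",
                     " %d ASE + %d imprinted gene(s)\n"),
              x$seed, x$n_chrom, x$chrom_len / 1e6, x$n_parents_a,
              x$n_parents_b, x$n_f1, x$n_sites, x$n_genes,
              nrow(x$sweep_windows), nrow(x$ase_genes),
              nrow(x$imprinted_genes)))
  invisible(x)
}

# Deterministic gene layout: genes tiled from a 150-kb margin at a fixed
# spacing, each with three exons over an 8-kb span.  No RNG involved, so the
# layout can be recomputed from the config alone.
GENE_SPAN <- 8000L
GENE_EXONS_REL <- data.table::data.table(start = c(0L, 3000L, 6000L),
                                         end = c(2000L, 5000L, 8000L))
GENE_CDS_REL <- data.table::data.table(start = c(200L, 3000L, 6000L),
                                       end = c(1900L, 5000L, 6200L))
GENE_SNP_OFFSETS <- c(200L, 1000L, 1800L, 3200L, 4200L, 4800L, 6100L,
                      7000L, 7800L)

sim_gene_layout <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  margin <- 150000L
  spacing <- max(GENE_SPAN + 1000L,
                 as.integer(floor((cfg$chrom_len - 2 * margin) / per_chrom)))
  rows <- list()
  k <- 0L
  for (ci in seq_len(cfg$n_chrom)) {
    n_here <- min(per_chrom, cfg$n_genes - (ci - 1L) * per_chrom)
    if (n_here <= 0L) break
    j <- seq_len(n_here)
    k <- k + 1L
    rows[[k]] <- data.table::data.table(
      gene_id = sprintf("gene_c%d_%03d", ci, j),
      chrom = cfg$chrom_names[ci],
      strand = ifelse(j %% 5L == 0L, "-", "+"),
      biotype = ifelse(j %% 10L == 0L, "noncoding_RNA",
                       ifelse(j %% 10L == 9L, "pseudogene", "protein_coding")),
      start = margin + (j - 1L) * spacing)
  }
  genes <- data.table::rbindlist(rows)
  genes[, end := start + GENE_SPAN]
  if (any(genes$end > cfg$chrom_len))
    stopf("gene layout exceeds chromosome length; increase chrom_len")
  exons <- genes[, .(start = start + GENE_EXONS_REL$start,
                     end = start + GENE_EXONS_REL$end), by = gene_id]
  cds <- genes[biotype == "protein_coding",
               .(start = start + GENE_CDS_REL$start,
                 end = start + GENE_CDS_REL$end), by = gene_id]
  if (nrow(cds)) {
    cds[, len := end - start]
    cds[, frame := (3L - (cumsum(data.table::shift(len, fill = 0L)) %% 3L)) %% 3L,
        by = gene_id]
    cds[, len := NULL]
  } else cds[, frame := integer()]
  gene_models(genes, exons, cds)
}

# The two default sweep windows are 150-kb windows on the 75-kb scan grid,
# each fully containing one gene (the future core-ASE truth genes).
default_sweep_windows <- function(cfg, gm) {
  pick <- function(ci, target) {
    g <- gm$genes[chrom == cfg$chrom_names[ci]]
    # first gene whose span fits inside a grid-aligned 150-kb window
    for (i in seq_len(nrow(g))) {
      w0 <- (g$start[i] %/% 75000L) * 75000L
      if (g$end[i] <= w0 + 150000L && w0 + 150000L <= cfg$chrom_len &&
          g$start[i] >= 1000000L)
        return(data.table::data.table(chrom = g$chrom[i], start = w0,
                                      end = w0 + 150000L, target = target,
                                      gene_id = g$gene_id[i]))
    }
    NULL
  }
  out <- data.table::rbindlist(list(
    pick(1L, "A"),
    if (cfg$n_chrom >= 2L) pick(2L, "B") else NULL))
  if (!nrow(out)) stopf("could not place default sweep windows")
  out
}

default_ase_genes <- function(cfg, gm) {
  sweep_gene <- cfg$sweep_windows$gene_id %||% character()
  sweep_gene <- sweep_gene[!is.na(sweep_gene)]
  neutral <- setdiff(gm$genes$gene_id, sweep_gene)
  # keep the neutral ASE genes well clear (>= 300 kb) of any sweep window
  far <- vapply(neutral, function(gid) {
    g <- gm$genes[gene_id == gid]
    sw <- cfg$sweep_windows[chrom == g$chrom]
    !nrow(sw) || all(g$start >= sw$end + 300000L | g$end <= sw$start - 300000L)
  }, TRUE)
  neutral <- neutral[far]
  picks <- if (length(neutral) >= 2L)
    neutral[utils::head(seq(2L, length(neutral), by = 3L), 6L)]
  else character()
  data.table::data.table(
    gene_id = c(sweep_gene, picks),
    theta = c(rep(0.8, length(sweep_gene)),
              rep(c(0.8, 0.2), length.out = length(picks))))
}

default_imprinted_genes <- function(cfg, gm) {
  used <- c(cfg$ase_genes$gene_id,
            cfg$sweep_windows$gene_id %||% character())
  free <- setdiff(gm$genes$gene_id, used)
  picks <- utils::tail(free, 2L)
  data.table::data.table(gene_id = picks,
                         theta = rep(c(0.98, 0.02), length.out = length(picks)))
}

#' Read or write a simulation config as JSON
#'
#' @param cfg a [sim_config()] object.
#' @param path JSON file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$chrom_names <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("sweep_windows", "ase_genes", "imprinted_genes"))
    if (!is.null(x[[nm]]))
      x[[nm]] <- data.table::as.data.table(x[[nm]])
  do.call(sim_config, x)
}
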