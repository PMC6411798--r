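# In-code fixture builders; everything is generated at test time.

vcf_fixture <- function(body_lines,
                        samples = c("A1", "A2", "B1", "B2"),
                        path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body_lines), path)
  path
}

default_popmap <- c(A1 = "YUNLING", A2 = "YUNLING", B1 = "NUBIAN",
                    B2 = "NUBIAN")

vcf_row <- function(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                    qual = 50, gts = c("0/0", "0/0", "1/1", "1/1"))
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT", gts),
        collapse = "\t")

# variant_sites built directly from a genotype matrix (alt dosage).
vs_fixture <- function(geno, pop, chrom = "chr1",
                       pos0 = seq_len(nrow(geno)) * 10L,
                       ref = "A", alt = "G", qual = 100) {
  n <- nrow(geno)
  colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  variant_sites(
    data.table::data.table(chrom = chrom, pos0 = pos0,
                           ref = rep_len(ref, n), alt = rep_len(alt, n),
                           qual = rep_len(qual, n)),
    geno,
    data.table::data.table(sample = colnames(geno), population = pop))
}

sam_fixture <- function(records, path = tempfile(fileext = ".sam"),
                        sq = "@SQ\tSN:chr1\tLN:100000") {
  writeLines(c("@HD\tVN:1.6", sq, records), path)
  path
}

sam_record <- function(qname = "r1", flag = 0, chrom = "chr1", pos = 1,
                       mapq = 60, cigar = "100M", seq = strrep("A", 100),
                       qual = strrep("?", nchar(seq)))
  paste(qname, flag, chrom, pos, mapq, cigar, "*", 0, 0, seq, qual,
        sep = "\t")

gff_fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# one + strand gene: exons [100,300) and [400,600), CDS [150,300)+[400,500)
simple_gene_gff <- function() gff_fixture(c(
  "chr1\tsrc\tgene\t101\t600\t.\t+\t.\tID=g1;biotype=protein_coding",
  "chr1\tsrc\tmRNA\t101\t600\t.\t+\t.\tID=g1.t1;Parent=g1",
  "chr1\tsrc\texon\t101\t300\t.\t+\t.\tParent=g1.t1",
  "chr1\tsrc\texon\t401\t600\t.\t+\t.\tParent=g1.t1",
  "chr1\tsrc\tCDS\t151\t300\t.\t+\t0\tParent=g1.t1",
  "chr1\tsrc\tCDS\t401\t500\t.\t+\t0\tParent=g1.t1"))

tiny_gene_models <- function() read_gene_models(simple_gene_gff())

# small sim config: no sweep windows, one tissue, light genome
small_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chrom = 1L, chrom_len = 1000000L,
               n_genes = 2L, n_sites = 20L, n_f1 = 2L,
               n_parents_a = 2L, n_parents_b = 2L,
               tissues = "liver", replicates_per_tissue = 1L,
               depth_mean = 40,
               sweep_windows = data.table::data.table(
                 chrom = character(), start = integer(), end = integer(),
                 target = character()))
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

count_row <- function(n_a, n_b, tissue = "liver", individual = "F1_1",
                      pos0 = 100L, gene_id = "g1")
  data.table::data.table(chrom = "chr1", pos0 = pos0, gene_id = gene_id,
                         individual = individual, tissue = tissue,
                         n_line_a = n_a, n_line_b = n_b)
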