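test_that("allele counting walks flags, qualities and CIGAR correctly", {
  site <- data.table::data.table(chrom = "chr1", pos0 = 110L, ref = "A",
                                 alt = "G")
  mkseq <- function(base, off, len = 100L) {
    s <- strrep("C", len); substr(s, off + 1L, off + 1L) <- base; s
  }
  reads <- read_sam(sam_fixture(c(
    sam_record("alt_read", 0, pos = 101, seq = mkseq("G", 10L)),
    sam_record("ref_read", 0, pos = 101, seq = mkseq("A", 10L)),
    sam_record("dup", 1024, pos = 101, seq = mkseq("G", 10L)),
    sam_record("secondary", 256, pos = 101, seq = mkseq("G", 10L)),
    sam_record("lowmapq", 0, pos = 101, mapq = 5, seq = mkseq("G", 10L)),
    sam_record("lowbaseq", 0, pos = 101, seq = mkseq("G", 10L),
               qual = paste0(strrep("?", 10), "#", strrep("?", 89))),
    sam_record("other_base", 0, pos = 101, seq = mkseq("T", 10L)))))
  counts <- extract_allele_counts(reads, site)
  expect_equal(counts$n_ref, 1L)
  expect_equal(counts$n_alt, 1L)
  expect_equal(counts$n_other, 1L)

  # site under a deletion contributes nothing
  del_reads <- read_sam(sam_fixture(
    sam_record("del", 0, pos = 101, cigar = "5M10D5M",
               seq = strrep("G", 10), qual = strrep("?", 10))))
  del_site <- data.table::data.table(chrom = "chr1", pos0 = 107L,
                                     ref = "A", alt = "G")
  got <- extract_allele_counts(del_reads, del_site)
  expect_equal(got$n_ref + got$n_alt + got$n_other, 0L)

  # insertion shifts the query offset: 10M5I90M, ref offset 12 -> query 17
  expect_equal(query_offset_at("10M5I90M", 100L, 112L), 17L)
  ins_seq <- strrep("C", 105)
  substr(ins_seq, 18, 18) <- "G"
  ins_reads <- read_sam(sam_fixture(
    sam_record("ins", 0, pos = 101, cigar = "10M5I90M", seq = ins_seq,
               qual = strrep("?", 105))))
  ins_site <- data.table::data.table(chrom = "chr1", pos0 = 112L,
                                     ref = "A", alt = "G")
  expect_equal(extract_allele_counts(ins_reads, ins_site)$n_alt, 1L)

  # absent chromosome: zero counts plus a warning
  far_site <- data.table::data.table(chrom = "chrZ", pos0 = 1L,
                                     ref = "A", alt = "G")
  expect_warning(zero <- extract_allele_counts(reads, far_site),
                 "absent")
  expect_equal(zero$n_ref + zero$n_alt, 0L)
})

test_that("replicate pooling sums within (site, individual, tissue)", {
  counts <- data.table::rbindlist(list(
    cbind(count_row(10L, 5L), replicate = 1L),
    cbind(count_row(8L, 7L), replicate = 2L)))
  pooled <- pool_replicates(counts)
  expect_equal(nrow(pooled), 1L)
  expect_equal(c(pooled$n_line_a, pooled$n_line_b), c(18L, 12L))
  expect_equal(nrow(pool_replicates(counts, scheme = "separate")), 2L)
  single <- pool_replicates(cbind(count_row(3L, 4L), replicate = 1L))
  expect_equal(c(single$n_line_a, single$n_line_b), c(3L, 4L))
})

test_that("depth filter boundaries match the published thresholds", {
  counts <- data.table::rbindlist(list(
    count_row(19L, 40L, pos0 = 1L),   # one allele below 20 -> filtered
    count_row(25L, 25L, pos0 = 2L),   # total exactly 50 -> kept
    count_row(100L, 5L, pos0 = 3L),   # strong imbalance
    count_row(20L, 30L, pos0 = 4L)))  # allele exactly 20 -> kept
  lit <- filter_counts(counts, mode = "literal")
  expect_equal(lit$pos0, c(2L, 4L))
  expect_equal(attr(lit, "n_filtered"), 2L)
  maj <- filter_counts(counts, mode = "major")
  expect_true(3L %in% maj$pos0)  # major mode keeps the imbalanced site
  expect_true(1L %in% maj$pos0)  # (19,40): major 40 >= 20, total 59 >= 50
})

test_that("binomial test equals closed forms and the enumeration oracle", {
  expect_equal(binomial_test(25L, 25L), 1)
  expect_equal(binomial_test(50L, 0L), 2 * 0.5^50, tolerance = 1e-12)
  expect_equal(binomial_test(35L, 15L), oracle_binom_two_sided(35L, 50L),
               tolerance = 1e-12)
  # doubling construction == minimum-likelihood construction (binom.test)
  for (k in c(0L, 3L, 10L, 29L, 30L)) {
    expect_equal(binomial_test(k, 60L - k),
                 stats::binom.test(k, 60L, 0.5)$p.value, tolerance = 1e-12)
  }
  expect_error(binomial_test(0L, 0L), "zero")
})

test_that("BH adjustment equals the step-up formula and reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric()), numeric())
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1]")
  set.seed(13)
  for (rep in 1:10) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))        # monotone in sorted-p order
    expect_true(all(q > 0 & q <= 1))
  }
})

test_that("site calls enforce strict ratio gates and the FDR threshold", {
  # a ratio of exactly 0.7 is never called, whatever the q-value
  counts <- count_row(70L, 30L)
  call <- call_ase_sites(counts)
  expect_equal(call$ratio, 0.7)
  expect_false(call$is_ase)
  # ratio 0.6 is never called
  expect_false(call_ase_sites(count_row(60L, 40L))$is_ase)
  # (90,10) among a batch of 100 nulls clears BH at 0.05
  nulls <- data.table::rbindlist(lapply(1:100, function(i)
    count_row(50L, 50L, pos0 = i * 10L)))
  batch <- data.table::rbindlist(list(nulls, count_row(90L, 10L, pos0 = 9999L)))
  calls <- call_ase_sites(batch)
  expect_true(calls[pos0 == 9999L, is_ase])
  expect_false(any(calls[pos0 != 9999L, is_ase]))
  # per-tissue FDR families: q-values computed within each tissue
  two_t <- data.table::rbindlist(list(
    count_row(90L, 10L, tissue = "liver"),
    count_row(55L, 45L, tissue = "bone")))
  ct <- call_ase_sites(two_t, fdr_scope = "per_tissue")
  expect_equal(ct[tissue == "liver", q_value],
               binomial_test(90L, 10L))
})

test_that("gene aggregation thresholds and imprint exclusion", {
  calls <- data.table::data.table(
    chrom = "chr1", pos0 = c(1L, 1L, 2L, 3L),
    gene_id = c("IGF2", "IGF2", "IGF2", "ACACA"),
    individual = c("i1", "i2", "i1", "i1"),
    tissue = "liver",
    is_ase = c(TRUE, FALSE, FALSE, TRUE))
  gene <- aggregate_to_genes(calls)
  expect_equal(gene[gene_id == "IGF2", n_tested_sites], 2L)
  expect_equal(gene[gene_id == "IGF2", n_ase_sites], 1L)
  expect_true(all(gene$is_ase_gene))
  # min_individuals = 2 with one supporting individual -> not ASE
  gene2 <- aggregate_to_genes(calls, min_individuals = 2L)
  expect_false(any(gene2$is_ase_gene))
  # exclusion is case-insensitive and removes genes from the final set
  excl <- exclude_imprinted(gene, c("igf2"))
  expect_equal(ase_gene_set(excl), "ACACA")
  expect_equal(attr(excl, "excluded_genes"), "IGF2")
  expect_equal(ase_gene_set(exclude_imprinted(gene, character())),
               c("ACACA", "IGF2"))
})

test_that("tissue specificity and shared sets", {
  ga <- data.table::data.table(
    gene_id = c("A", "B", "B"), tissue = c("liver", "liver", "bone"),
    is_ase_gene = TRUE)
  ov <- tissue_overlap_summary(ga)
  expect_equal(ov$per_tissue[tissue == "liver", specificity], 0.5)
  expect_equal(ov$per_tissue[tissue == "bone", specificity], 0)
  expect_equal(ov$shared_all, "B")
  single <- tissue_overlap_summary(ga[tissue == "liver"])
  expect_equal(single$per_tissue$specificity, 1)
  none <- tissue_overlap_summary(
    data.table::data.table(gene_id = "A", tissue = "liver",
                           is_ase_gene = FALSE))
  expect_true(is.na(none$per_tissue$specificity))
})

test_that("imprinted genes are detected by the statistics, then excluded", {
  # near-monoallelic sites need the major-allele depth mode: under the
  # literal filter a 0.98-ratio site at moderate depth loses its minor
  # allele to the per-allele floor
  cfg <- small_sim_config(seed = 21, depth_mean = 120,
                          n_genes = 6L, chrom_len = 3000000L,
                          ase_genes = data.table::data.table(
                            gene_id = "gene_c1_001", theta = 0.8),
                          imprinted_genes = data.table::data.table(
                            gene_id = c("gene_c1_003", "gene_c1_005"),
                            theta = c(0.98, 0.02)))
  ds <- simulate_dataset(cfg)
  res_keep <- run_ase_detection(ds$counts, imprinted = character(),
                                filter_mode = "major")
  expect_true(all(c("gene_c1_003", "gene_c1_005") %in% res_keep$ase_genes))
  res_excl <- run_ase_detection(ds$counts, imprinted = ds$imprinted,
                                filter_mode = "major")
  expect_false(any(ds$imprinted %in% res_excl$ase_genes))
  expect_true("gene_c1_001" %in% res_excl$ase_genes)
})
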