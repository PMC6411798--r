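pop4 <- c("YUNLING", "YUNLING", "NUBIAN", "NUBIAN")

test_that("QUAL filter boundary: < 30 removed, exactly 30 kept", {
  vs <- vs_fixture(matrix(0L, 3, 4), pop = pop4, qual = c(29.9, 30, 45))
  kept <- filter_by_qual(vs)
  expect_equal(kept$sites$qual, c(30, 45))
  expect_equal(attr(kept, "n_filtered"), 1L)
  empty <- filter_by_qual(subset_sites(vs, integer()))
  expect_equal(n_sites(empty), 0L)
})

test_that("strict discriminating assignment and line-of-origin alleles", {
  geno <- rbind(
    c(0L, 0L, 2L, 2L),   # A hom-ref, B hom-alt -> discriminating
    c(0L, 1L, 2L, 2L),   # het in line A -> not
    c(2L, 2L, 0L, 0L),   # A hom-alt, B hom-ref -> discriminating, swapped
    c(0L, 0L, 0L, 0L),   # monomorphic -> not
    c(0L, NA, 2L, 2L))   # missing with max_missing_frac = 0 -> not
  vs <- vs_fixture(geno, pop = pop4, ref = "A", alt = "G")
  disc <- assign_discriminating_snps(vs)
  expect_equal(disc$pos0, c(10L, 30L))
  expect_equal(disc$allele_a, c("A", "G"))
  expect_equal(disc$allele_b, c("G", "A"))
  # relaxing the missing tolerance admits the partially missing site
  disc2 <- assign_discriminating_snps(vs, max_missing_frac = 0.5)
  expect_true(50L %in% disc2$pos0)
})

test_that("frequency mode uses the allele-frequency difference", {
  # A freq 0.9 (5 samples), B freq 0.05 (10 samples): |diff| = 0.85 >= 0.8
  geno <- matrix(c(2L, 2L, 2L, 2L, 1L, 1L, rep(0L, 9)), nrow = 1)
  vs <- vs_fixture(geno, pop = rep(c("YUNLING", "NUBIAN"), c(5, 10)))
  disc <- assign_discriminating_snps(vs, mode = "frequency")
  expect_equal(nrow(disc), 1L)
  expect_equal(disc$allele_a, "G")  # majority allele of line A is alt
  expect_equal(disc$allele_b, "A")
  disc_strict <- assign_discriminating_snps(vs, mode = "strict")
  expect_equal(nrow(disc_strict), 0L)
})

test_that("strict assignment equals the exhaustive per-site oracle", {
  set.seed(20240301)
  n <- 300L
  geno <- matrix(sample(c(0L, 1L, 2L, NA), n * 6, replace = TRUE,
                        prob = c(0.4, 0.15, 0.4, 0.05)), n, 6)
  vs <- vs_fixture(geno, pop = rep(c("YUNLING", "NUBIAN"), c(3, 3)),
                   pos0 = seq_len(n))
  disc <- assign_discriminating_snps(vs)
  expected <- vapply(seq_len(n), function(i)
    oracle_strict_discriminating(geno[i, 1:3], geno[i, 4:6]), TRUE)
  expect_equal(sort(disc$pos0), which(expected))
})

test_that("annotation precedence and distance windows", {
  gm <- tiny_gene_models()  # + strand gene g1: exons [100,300), [400,600)
  snps <- data.table::data.table(
    chrom = "chr1",
    pos0 = c(150L,    # exonic
             350L,    # intronic (between exons, > 2 bp from boundaries)
             300L,    # first intron base, 1 bp past exon end -> splice
             301L,    # 2 bp past exon end -> splice (boundary)
             302L,    # 3 bp -> intronic
             99L,     # 1 bp before gene start -> upstream (+ strand)
             50L,     # 500 bp upstream would be 5' of start; still upstream
             700L,    # past gene end within 1 kb -> downstream
             50000L), # far away -> intergenic
    ref = "A", alt = "G")
  ann <- annotate_snps(snps, gm)
  expect_equal(ann$per_snp$category,
               c("exonic", "intronic", "splice_region", "splice_region",
                 "intronic", "upstream", "upstream", "downstream",
                 "intergenic"))
  expect_equal(ann$per_snp$gene_id[1], "g1")
  expect_equal(ann$per_snp$gene_id[9], "")
  # partition: each SNP exactly one category; tallies sum to input size
  summ <- annotation_category_summary(ann)
  expect_equal(sum(summ$n), nrow(snps))
})

test_that("minus-strand flanks are strand-aware", {
  gff <- gff_fixture(c(
    "chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tID=gm",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t-\t.\tID=gm.t;Parent=gm",
    "chr1\tsrc\texon\t1001\t2000\t.\t-\t.\tParent=gm.t"))
  gm <- read_gene_models(gff)
  snps <- data.table::data.table(chrom = "chr1", pos0 = c(2500L, 500L),
                                 ref = "A", alt = "G")
  ann <- annotate_snps(snps, gm)
  # 3' end in genome coordinates is 5' of a minus-strand gene
  expect_equal(ann$per_snp$category, c("upstream", "downstream"))
})

test_that("coding-change classification against the standard code", {
  expect_equal(classify_coding_change("GTT", 3, "C"), "synonymous")
  expect_equal(classify_coding_change("TAC", 3, "A"), "stopgain")
  expect_equal(classify_coding_change("TGA", 3, "C"), "stoploss")
  expect_equal(classify_coding_change("AAA", 1, "G"), "nonsynonymous")
})

test_that("genomic coding change walks CDS, strand and UTR correctly", {
  gm <- tiny_gene_models()  # CDS [150,300) + [400,500), frame 0, + strand
  genome <- list(chr1 = strrep("ACGT", 200))  # 800 bp repeating
  # CDS base 0 is genome pos0 150 ('C' of ACGT phase): codon from pos 150
  codon1 <- substr(genome$chr1, 151, 153)
  ref1 <- substr(genome$chr1, 151, 151)
  got <- coding_change_for_site("chr1", 150L, ref1, "G", gm, "g1", genome)
  expect_equal(got, classify_coding_change(codon1, 1, "G"))
  # exonic but outside CDS (UTR) -> none
  expect_equal(coding_change_for_site("chr1", 120L,
                                      substr(genome$chr1, 121, 121), "A",
                                      gm, "g1", genome), "none")
  # splice across CDS parts: CDS position 150 total in first chunk = 150 bp,
  # so pos0 400 is CDS base 150 -> codon 50, phase 0
  ref2 <- substr(genome$chr1, 401, 401)
  alt2 <- setdiff(c("A", "C", "G", "T"), ref2)[1]
  spliced <- paste0(substr(genome$chr1, 151, 300), substr(genome$chr1, 401, 500))
  codon2 <- substr(spliced, 151, 153)
  expect_equal(coding_change_for_site("chr1", 400L, ref2, alt2, gm, "g1",
                                      genome),
               classify_coding_change(codon2, 1, alt2))
})

test_that("minus-strand classification equals the reverse-complement
           construction (metamorphic)", {
  set.seed(99)
  L <- 120L
  genome_fwd <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = "")
  # minus-strand gene with CDS [30, 90) on the forward genome
  gff_minus <- gff_fixture(c(
    sprintf("chr1\tsrc\tgene\t%d\t%d\t.\t-\t.\tID=g", 21, 100),
    sprintf("chr1\tsrc\tmRNA\t%d\t%d\t.\t-\t.\tID=g.t;Parent=g", 21, 100),
    sprintf("chr1\tsrc\texon\t%d\t%d\t.\t-\t.\tParent=g.t", 21, 100),
    sprintf("chr1\tsrc\tCDS\t%d\t%d\t.\t-\t0\tParent=g.t", 31, 90)))
  gm_minus <- read_gene_models(gff_minus)
  # mirrored + strand gene on the reverse-complemented genome
  gff_plus <- gff_fixture(c(
    sprintf("chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=g", L - 100 + 1, L - 21 + 1),
    sprintf("chr1\tsrc\tmRNA\t%d\t%d\t.\t+\t.\tID=g.t;Parent=g",
            L - 100 + 1, L - 21 + 1),
    sprintf("chr1\tsrc\texon\t%d\t%d\t.\t+\t.\tParent=g.t",
            L - 100 + 1, L - 21 + 1),
    sprintf("chr1\tsrc\tCDS\t%d\t%d\t.\t+\t0\tParent=g.t",
            L - 90 + 1, L - 31 + 1)))
  gm_plus <- read_gene_models(gff_plus)
  genome_rev <- list(chr1 = revcomp(genome_fwd))
  for (pos0 in c(30L, 45L, 67L, 89L)) {
    ref <- substr(genome_fwd, pos0 + 1L, pos0 + 1L)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[2]
    mirror_pos0 <- L - 1L - pos0
    got_minus <- coding_change_for_site("chr1", pos0, ref, alt, gm_minus,
                                        "g", list(chr1 = genome_fwd))
    got_plus <- coding_change_for_site("chr1", mirror_pos0,
                                       chartr("ACGT", "TGCA", ref),
                                       chartr("ACGT", "TGCA", alt),
                                       gm_plus, "g", genome_rev)
    expect_equal(got_minus, got_plus, label = paste("pos", pos0))
  }
})

test_that("transition/transversion summary", {
  snps <- data.table::data.table(ref = c("A", "C", "A", "G"),
                                 alt = c("G", "T", "C", "T"))
  s <- transition_transversion_summary(snps)
  expect_equal(c(s$n_ts, s$n_tv), c(2L, 2L))
  expect_equal(s$ratio, 1)
  only_ts <- transition_transversion_summary(
    data.table::data.table(ref = "A", alt = "G"))
  expect_true(is.na(only_ts$ratio))
  mix <- data.table::data.table(
    ref = c("A", "C", "G", "T", "A", "C", "A", "A", "G"),
    alt = c("G", "T", "A", "C", "G", "T", "C", "T", "T"))
  expect_equal(transition_transversion_summary(mix)$ratio, 2)
})

test_that("per-gene SNP counts include both genes of an overlap", {
  gff <- gff_fixture(c(
    "chr1\tsrc\tgene\t101\t600\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t101\t600\t.\t+\t.\tID=gA.t;Parent=gA",
    "chr1\tsrc\texon\t101\t600\t.\t+\t.\tParent=gA.t",
    "chr1\tsrc\tgene\t401\t900\t.\t+\t.\tID=gB",
    "chr1\tsrc\tmRNA\t401\t900\t.\t+\t.\tID=gB.t;Parent=gB",
    "chr1\tsrc\texon\t401\t900\t.\t+\t.\tParent=gB.t"))
  gm <- read_gene_models(gff)
  snps <- data.table::data.table(chrom = "chr1",
                                 pos0 = c(450L, 450L, 450L, 50000L),
                                 ref = "A", alt = "G")
  ann <- annotate_snps(snps, gm)
  counts <- per_gene_snp_counts(ann)
  expect_equal(counts[gene_id == "gA", n_snps], 3L)
  expect_equal(counts[gene_id == "gB", n_snps], 3L)
  only_intergenic <- annotate_snps(
    data.table::data.table(chrom = "chr9", pos0 = 1L, ref = "A", alt = "G"),
    gm)
  expect_equal(nrow(per_gene_snp_counts(only_intergenic)), 0L)
})
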