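---
title: "Methods: ASE detection, sweep scanning and the synthetic world"
author: "aseScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ASE detection, sweep scanning and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics: the models
and their assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed. It states
no empirical result that the test suite and the pipeline do not themselves
compute.

## 1. The inference

The pipeline targets crosses between two divergent populations (the
motivating design: six dams of one breed, four sires of another, nine F1
hybrids, RNA from six tissues with two technical replicates each). Three
evidence streams are combined:

* **Discriminating SNPs.** A site discriminates the lines when every
  genotyped line-A parent is homozygous for one allele and every line-B
  parent homozygous for the other (strict mode). Every F1 is then
  heterozygous at that site and the breed of origin of each RNA read is
  known. A frequency mode (|freq_A − freq_B| ≥ 0.8) is provided for
  panels where fixed differences are too rare, but strict mode is the
  default because the ASE stage needs guaranteed heterozygosity and
  unambiguous line-of-origin.
* **Selective sweeps.** Windowed Fst between the parental populations and
  pooled heterozygosity Hp within each, both Z-standardised; windows in
  the extreme 1% tail are merged into candidate regions.
* **ASE.** Exact binomial tests of per-site allelic read fractions in the
  F1s, FDR-corrected, with effect-size gates.

A *core-ASE* gene is ASE in at least one tissue **and** overlaps at least
one sweep region under any criterion. The intersection is deliberately
unconditional — the ASE tissue does not have to "match" the swept
population, because cis-regulatory variants fixed in either breed can
surface in any tissue; the per-gene report records which criteria
contributed so stricter readers can re-filter.

## 2. Statistical cores

**Weir–Cockerham Fst.** For each biallelic site the three variance
components are computed for two populations of diploids: `a` (among
populations), `b` (among individuals within populations), `c` (within
individuals), using sample sizes, allele frequencies and observed
heterozygote frequencies per population. Per-site Fst is a/(a+b+c); a
window's Fst is the *ratio of sums* Σa/Σ(a+b+c) over its sites (the
"weighted" estimator), never the mean of per-site ratios. Sites where a
population has no genotyped individual, or where the denominator is zero
(monomorphic), yield NA and are excluded from window sums. The test suite
holds both the per-site components and the window ratio to an
independently coded scalar implementation at 1e-12.

**Pooled heterozygosity.** Hp = 2·ΣnMAJ·ΣnMIN/(ΣnMAJ+ΣnMIN)², where nMAJ
and nMIN are per-site major/minor allele counts from the population's
genotypes, summed over the window. The algebraic maximum 2ab/(a+b)² is
0.5; a window of monomorphic sites gives 0. Hp is computed per population
because a sweep depresses heterozygosity only in the swept breed.

**Z-transformation and tail selection.** Windows with fewer than
`min_snps = 10` informative sites are ineligible (variance of both
statistics explodes in near-empty windows; the source methods are silent
here). Over eligible windows, z = (x − mean)/sd with the sample (n−1) sd;
an all-equal vector is a hard error rather than a silent zero-division.
Selection uses nearest-rank quantiles with closed thresholds, so ties at
the boundary are all included. The low-heterozygosity screen takes the
*lower tail* of ZHp, not |ZHp|: the stated intent is lowest
heterozygosity, and the absolute value would also capture
excess-heterozygosity windows. The |ZHp| variant can be recovered by
screening both tails.

**Window geometry.** The default is the 150-kb window / 75-kb step
sliding geometry; the non-overlapping 100-kb variant that the motivating
analysis also mentions is available as `window = 100000, step = 100000`.
The package does not attempt to decide which variant produced any
published table — geometry is a parameter.

**Binomial ASE test.** p = min(1, 2·min(P(X ≤ k), P(X ≥ k))) with
X ~ Bin(n, ½). For this symmetric null the doubling construction equals
the minimum-likelihood construction; the tests assert both equalities and
exhaustive-enumeration agreement for all totals ≤ 60 at 1e-12.
Benjamini–Hochberg is the step-up q(i) = min_{j≥i} p(j)·m/j capped at 1,
checked against an independent implementation. FDR families are
per-tissue by default (each tissue's tests form one presentation unit);
`fdr_scope = "global"` pools them.

**Calls and aggregation.** A site is ASE iff q < 0.05 *and* its line-A
fraction is strictly outside [0.3, 0.7]; a ratio of exactly 0.7 is never
called. Tests run per individual; a site counts as ASE if significant in
at least one individual, and a gene is ASE in a tissue when ≥
`min_ase_sites` (default 1) such sites are supported by ≥
`min_individuals` (default 1) individuals. These thresholds are
configurable because the gene-aggregation rule behind published gene
counts is not stated anywhere authoritative.

## 3. Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_qual` | 30 | Phred | published filter "QUAL < 30 removed"; boundary kept at exactly 30 |
| `upstream_downstream_bp` | 1000 | bp | common annotator convention for flank categories |
| `splice_bp` | 2 | bp | intronic bases within 2 bp of an exon boundary are splice region |
| `window`, `step` | 150000, 75000 | bp | stated sliding geometry; 100 kb non-overlapping preset available |
| `top_frac` | 0.01 | — | extreme 1% tail of the empirical Z distribution |
| `min_snps` | 10 | sites | eligibility floor for window statistics |
| `min_mapq`, `min_baseq` | 20, 20 | Phred | conventional counting thresholds; the original counting script's parameters are unpublished |
| `min_allele_depth`, `min_total_depth` | 20, 50 | reads | published depth filters; "<" semantics, so 20 and 50 pass |
| `filter_mode` | `"literal"` | — | see §5: literal reading caps detectable imbalance; `"major"` provided |
| `ratio_hi`, `ratio_lo`, `q_threshold` | 0.7, 0.3, 0.05 | — | published call criteria, strict comparisons |
| `depth_mean` | 80 | reads/site/replicate | generator: deep RNA-seq at informative sites |
| `overdispersion` | 0.01 | ρ ∈ [0,1) | generator: mild technical overdispersion (see §5) |

## 4. The synthetic world

The generator emulates the *statistical structure* the analysis assumes,
not sequencing physics:

* Two parental populations; neutral sites draw allele frequencies
  independently per population from Beta(0.5, 0.5) — a U-shaped site
  frequency spectrum that yields many near-fixed and some intermediate
  sites, i.e. realistic variation in per-site Fst and Hp.
* Planted sweep windows (default: two 150-kb windows aligned to the scan
  grid, one per chromosome, each containing one gene): the target
  population draws Beta(40, 1) (mean ≈ 0.976, near fixation → low Hp),
  the other Beta(1, 40) (→ high Fst). This plants the joint signature the
  scan screens for without simulating haplotype history.
* Each gene carries four strict fixed-difference SNPs in its exons
  (line A = reference), spaced ≥ 150 bp so synthetic 100-bp reads never
  span two sites and counter round-trips are exact.
* F1 genotypes are Mendelian draws (one allele from a cyclically assigned
  dam, one from a sire); fixed differences force heterozygosity.
* RNA counts per (site, individual, tissue, replicate): depth ~
  Poisson(`depth_mean`); line-A count ~ BetaBinomial(depth, θ_gene, ρ)
  with θ = 0.5 for neutral genes, 0.8/0.2 for cis-regulated genes, and
  0.98/0.02 for imprinted genes (written to the exclusion list).
* QUAL ~ truncated Normal(220, 40) with a 5% low-quality fraction drawn
  from Uniform(5, 29.9) so the quality filter has real work.
* Alternate alleles are transitions with probability 0.694, matching the
  transition excess typical of mammalian resequencing, so the Ts/Tv
  summary produces sensible values on synthetic data.
* FPKM ~ logNormal(1, 1), with ASE genes at logNormal(2, 1) and
  pseudogenes near zero: the world assumes imbalanced genes sit among the
  better-expressed genes — which is also the regime where they are
  detectable.

**Not emulated:** sequencing error, reference-mapping bias, RNA editing,
linkage disequilibrium and haplotype structure, variable gene length and
expression-dependent depth, X chromosome. A green recovery test therefore
establishes that the *inference machinery* is correct on data satisfying
its assumptions — not that those assumptions hold on any real dataset.

Every output is a pure function of the configuration (including the
seed): each stage seeds the RNG from `derive_seed(seed, stage_tag)`, and
all writers emit bytes deterministically, which the acceptance suite
checks with checksums.

## 5. Numerical choices and known limitations

* **Internal coordinates** are 0-based half-open everywhere; VCF/GFF3/SAM
  (1-based) are converted at the I/O boundary, BED passes through
  unchanged. This keeps window arithmetic and overlap tests to a single
  convention.
* **Phase is ignored** (`0|1` ≡ `0/1`): at strict discriminating sites
  the line of origin is determined by the allele itself.
* **Multiallelic and indel records are skipped** and tallied, never
  parsed: every downstream statistic is defined on biallelic SNPs.
* **Multi-transcript genes** collapse to the exon union plus the
  longest-CDS transcript; reporting is gene-level throughout. A SNP
  overlapping two genes is annotated and counted for both; the single
  summary category follows the precedence exonic > splice_region >
  intronic > up/downstream > intergenic.
* **The literal depth filter caps detectable imbalance.** Requiring each
  allele ≥ 20 reads means a kept site can never show a ratio above
  (T−20)/T; near-monoallelic (imprinted-like) sites at moderate depth are
  silently removed before testing. The `major` mode (deeper allele ≥ 20)
  preserves them, and the test suite demonstrates imprinted-gene
  detection-then-exclusion under that mode. Both readings of the
  published "and" are implemented; neither is asserted as the original
  intent.
* **The binomial test is anti-conservative under overdispersion.** The
  generator's default ρ = 0.01 deliberately exceeds the binomial model,
  and at the default depth a handful of θ = 0.5 genes per genome are
  called ASE — a quantified reminder of why beta-binomial tests exist.
  The type-I acceptance criterion is evaluated at ρ = 0, the test's own
  null; the end-to-end core-ASE criterion absorbs the extra calls because
  false ASE genes rarely coincide with sweep regions.
* **Tissue specificity** is |ASE(t) \\ ∪_{s≠t} ASE(s)| / |ASE(t)|, and the
  shared set is the intersection across all tissues (a gene present in
  every tissue is "shared", even with only two tissues).
* **Sample-size floor:** the Weir–Cockerham components need ≥ 2 genotyped
  individuals per population; with the emulated 6 + 4 panel the
  estimator's variance is large at single sites, which is precisely why
  windows (and the Σa/ΣΣ weighting) are used.
* The expression comparison uses a Wilcoxon rank-sum test; the claim it
  supports ("ASE genes are higher expressed") was published without a
  named test, and a rank test is robust to FPKM's heavy tail.
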