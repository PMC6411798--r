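# Windowed selective-sweep scan over the two parental populations:
# Weir-Cockerham Fst (variance components, window-weighted as sum(a) /
# sum(a+b+c)) and pooled heterozygosity Hp = 2 * sum(nMAJ) * sum(nMIN) /
# (sum(nMAJ) + sum(nMIN))^2, each Z-standardised across the genome, with
# nearest-rank tail selection and region merging.

#' Weir-Cockerham variance components for one or more sites
#'
#' Implements the diploid two-level (no inbreeding decomposition beyond
#' heterozygote frequency) Weir & Cockerham (1984) estimator for two
#' populations: `a` among populations, `b` among individuals within
#' populations, `c` within individuals.  Per-site Fst is `a / (a + b + c)`.
#'
#' @param geno integer matrix (sites x samples) of alternate-allele dosage
#'   with NA for missing genotypes.
#' @param pop factor/character of population labels, length `ncol(geno)`,
#'   exactly two levels.
#' @return data.table with columns `a`, `b`, `c`, `fst` (NA where the
#'   denominator is zero or a population has fewer than 1 genotyped
#'   individual; sites with a population having < 1 genotyped sample are
#'   tallied in attribute `n_skipped`).
#' @export
site_fst_components <- function(geno, pop) {
  pops <- unique(pop)
  if (length(pops) != 2L) stopf("exactly 2 populations required")
  g1 <- geno[, pop == pops[1], drop = FALSE]
  g2 <- geno[, pop == pops[2], drop = FALSE]
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  bad <- n1 < 1L | n2 < 1L | !is.finite(nbar) | nbar <= 1
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  denom <- a + b + cc
  fst <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  out <- data.table::data.table(a = a, b = b, c = cc, fst = fst)
  data.table::setattr(out, "n_skipped", sum(n1 < 1L | n2 < 1L))
  out[]
}

#' Tile a genome with sliding windows
#'
#' Windows are anchored at multiples of `step` from position 0 of each
#' chromosome; the last window of a chromosome may be truncated.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window window size in bp (default 150 kb).
#' @param step step size in bp (default 75 kb; set `step = window` for
#'   non-overlapping windows).
#' @return data.table `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(chrom_lengths, window = 150000L, step = 75000L) {
  stopifnot(window >= step, step >= 1L)
  data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + window, as.integer(len)))
  }))
}

window_site_map <- function(windows, sites_chrom, sites_pos0) {
  # rows of `windows` matched to site indices; sliding windows mean a site
  # can fall in up to window/step windows
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    out[[i]] <- which(sites_chrom == windows$chrom[i] &
                        sites_pos0 >= windows$start[i] &
                        sites_pos0 < windows$end[i])
  }
  out
}

#' Window-weighted Fst
#'
#' The window estimate is the ratio of sums `sum(a) / sum(a + b + c)` over
#' the window's sites (the "weighted" Fst of the variance-component
#' estimator), not the mean of per-site ratios.
#'
#' @param windows data.table from [make_windows()].
#' @param comp per-site components from [site_fst_components()].
#' @param sites data.table with `chrom`, `pos0` aligned with `comp`.
#' @return `windows` with added `n_snps` (sites with defined components)
#'   and `fst` (NA for empty windows).
#' @export
window_fst <- function(windows, comp, sites) {
  wmap <- window_site_map(windows, sites$chrom, sites$pos0)
  out <- data.table::copy(windows)
  out[, c("n_snps", "fst") := {
    res <- vapply(wmap, function(idx) {
      a <- comp$a[idx]; d <- comp$a[idx] + comp$b[idx] + comp$c[idx]
      ok <- !is.na(d)
      if (!any(ok) || sum(d[ok]) == 0) c(sum(ok), NA_real_)
      else c(sum(ok), sum(a[ok]) / sum(d[ok]))
    }, numeric(2))
    list(as.integer(res[1, ]), res[2, ])
  }]
  out[]
}

#' Pooled heterozygosity per window
#'
#' Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2, where nMAJ
#' and nMIN are the per-site major and minor allele counts in the
#' population, summed over the window's sites.  Bounded in [0, 0.5].
#'
#' @param windows data.table from [make_windows()].
#' @param geno genotype matrix (sites x samples) for one population.
#' @param sites data.table with `chrom`, `pos0` aligned with `geno`.
#' @return numeric vector of Hp per window (NA for windows with no
#'   genotyped site).
#' @export
window_hp <- function(windows, geno, sites) {
  n_ok <- rowSums(!is.na(geno))
  n_alt <- rowSums(geno, na.rm = TRUE)
  n_ref <- 2L * n_ok - n_alt
  n_maj <- pmax(n_ref, n_alt)
  n_min <- pmin(n_ref, n_alt)
  wmap <- window_site_map(windows, sites$chrom, sites$pos0)
  vapply(wmap, function(idx) {
    idx <- idx[n_ok[idx] > 0L]
    if (!length(idx)) return(NA_real_)
    smaj <- sum(n_maj[idx]); smin <- sum(n_min[idx])
    2 * smaj * smin / (smaj + smin)^2
  }, 0)
}

#' Z-standardise a statistic across windows
#'
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation; NA
#' values are excluded from mean/sd and preserved in place.
#'
#' @param x numeric vector.
#' @param name statistic name used in error messages.
#' @return numeric vector of z-scores.
#' @export
z_transform <- function(x, name = deparse(substitute(x))) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stopf("z_transform(%s): need >= 2 finite values", name)
  s <- stats::sd(x[ok])
  if (s == 0) stopf("z_transform(%s): zero spread", name)
  (x - mean(x[ok])) / s
}

#' Compute the full window scan table
#'
#' @param vs parental [variant_sites()] (two populations).
#' @param window,step window geometry in bp; the default 150 kb / 75 kb
#'   sliding geometry can be swapped for the non-overlapping 100 kb preset
#'   via `window = 100000, step = 100000`.
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   last site position + 1 per chromosome.
#' @param min_snps windows with fewer informative SNPs are ineligible for
#'   z-scoring and tail selection (their z columns are NA).
#' @return data.table: chrom, start, end, n_snps, fst, hp_a, hp_b, z_fst,
#'   z_hp_a, z_hp_b, eligible.
#' @export
sweep_scan <- function(vs, window = 150000L, step = 75000L,
                       chrom_lengths = NULL, min_snps = 10L) {
  if (is.null(chrom_lengths)) {
    cl <- vs$sites[, .(len = max(pos0) + 1L), by = chrom]
    chrom_lengths <- stats::setNames(cl$len, cl$chrom)
  }
  windows <- make_windows(chrom_lengths, window, step)
  comp <- site_fst_components(vs$geno, vs$samples$population)
  out <- window_fst(windows, comp, vs$sites)
  a_cols <- vs$samples$population == "YUNLING"
  out[, hp_a := window_hp(windows, vs$geno[, a_cols, drop = FALSE], vs$sites)]
  out[, hp_b := window_hp(windows, vs$geno[, !a_cols, drop = FALSE], vs$sites)]
  out[, eligible := n_snps >= min_snps]
  for (col in c("fst", "hp_a", "hp_b")) {
    z <- rep(NA_real_, nrow(out))
    vals <- ifelse(out$eligible, out[[col]], NA_real_)
    z[out$eligible] <- z_transform(vals, col)[out$eligible]
    out[, paste0("z_", col) := z]
  }
  out[]
}

#' Select extreme windows by nearest-rank tail quantile
#'
#' `z_fst_high` keeps windows at or above the upper `top_frac` empirical
#' quantile of `z_fst`; `z_hp_low` keeps windows at or below the lower
#' `top_frac` quantile of the chosen population's `z_hp` (the lowest
#' heterozygosity, i.e. the most negative z).  Quantiles are nearest-rank
#' over eligible windows and ties at the threshold are all included.
#'
#' @param scan table from [sweep_scan()].
#' @param statistic `"z_fst_high"` or `"z_hp_low"`.
#' @param population `"A"` or `"B"`, for `z_hp_low`.
#' @param top_frac tail fraction (default 0.01).
#' @return the selected rows of `scan`, with a `criterion` column.
#' @export
select_extreme_windows <- function(scan, statistic = c("z_fst_high",
                                                       "z_hp_low"),
                                   population = c("A", "B"),
                                   top_frac = 0.01) {
  statistic <- match.arg(statistic)
  population <- match.arg(population)
  elig <- scan[eligible == TRUE]
  if (statistic == "z_fst_high") {
    z <- elig$z_fst
    crit <- "high_zfst"
  } else {
    z <- if (population == "A") elig$z_hp_a else elig$z_hp_b
    crit <- paste0("low_zhp_pop", population)
  }
  z_ok <- z[!is.na(z)]
  if (!length(z_ok)) {
    warning("no eligible windows for ", crit)
    return(cbind(elig[0], criterion = character()))
  }
  n <- length(z_ok)
  if (statistic == "z_fst_high") {
    # nearest-rank upper quantile: the ceiling(n * top_frac) largest values
    k <- max(1L, as.integer(ceiling(n * top_frac)))
    thr <- sort(z_ok, decreasing = TRUE)[k]
    sel <- elig[!is.na(z) & z >= thr]
  } else {
    k <- max(1L, as.integer(ceiling(n * top_frac)))
    thr <- sort(z_ok)[k]
    sel <- elig[!is.na(z) & z <= thr]
  }
  sel[, criterion := crit]
  sel[]
}

#' Merge selected windows into sweep regions
#'
#' Overlapping or bookended windows on the same chromosome are merged;
#' `peak_z` records the most extreme member z-score (maximum for the
#' high-Fst criterion, minimum for low-Hp).
#'
#' @param selected output of [select_extreme_windows()].
#' @return data.table: chrom, start, end, criterion, n_windows, peak_z.
#' @export
merge_regions <- function(selected) {
  if (!nrow(selected))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), criterion = character(),
                                  n_windows = integer(), peak_z = numeric()))
  crit <- selected$criterion[1]
  zcol <- switch(crit, high_zfst = "z_fst", low_zhp_popA = "z_hp_a",
                 low_zhp_popB = "z_hp_b")
  s <- selected[order(chrom, start)]
  region_id <- integer(nrow(s))
  rid <- 0L
  cur_end <- -1L
  cur_chrom <- ""
  for (i in seq_len(nrow(s))) {
    if (s$chrom[i] != cur_chrom || s$start[i] > cur_end) {
      rid <- rid + 1L
      cur_chrom <- s$chrom[i]
      cur_end <- s$end[i]
    } else cur_end <- max(cur_end, s$end[i])
    region_id[i] <- rid
  }
  s[, .rid := region_id]
  s[, .(chrom = chrom[1], start = min(start), end = max(end),
        criterion = crit, n_windows = .N,
        peak_z = if (crit == "high_zfst") max(get(zcol)) else min(get(zcol))),
    by = .rid][, .rid := NULL][]
}

#' Attach overlapping genes to sweep regions
#'
#' A gene belongs to a region iff their half-open intervals overlap by at
#' least 1 bp.
#'
#' @param regions data.table from [merge_regions()].
#' @param gm a [gene_models()] object.
#' @return list with `regions` (plus `n_genes` and semicolon-joined
#'   `genes`) and `region_genes` (one row per region/gene pair).
#' @export
genes_in_regions <- function(regions, gm) {
  pairs <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- gm$genes[chrom == regions$chrom[i] & start < regions$end[i] &
                    end > regions$start[i]]
    pairs[[i]] <- if (nrow(g))
      data.table::data.table(region = i, gene_id = g$gene_id)
    else data.table::data.table(region = integer(), gene_id = character())
  }
  region_genes <- data.table::rbindlist(pairs)
  out <- data.table::copy(regions)
  out[, n_genes := 0L]
  out[, genes := ""]
  if (nrow(region_genes)) {
    agg <- region_genes[, .(n_genes = .N,
                            genes = paste(gene_id, collapse = ";")),
                        by = region]
    out[agg$region, `:=`(n_genes = agg$n_genes, genes = agg$genes)]
  }
  list(regions = out[], region_genes = region_genes)
}

#' Run the full sweep scan and selection
#'
#' Applies the three screens (high ZFst; low ZHp in each population),
#' merges each selection into regions and attaches genes.
#'
#' @param vs parental [variant_sites()].
#' @param gm a [gene_models()] object.
#' @inheritParams sweep_scan
#' @inheritParams select_extreme_windows
#' @return list: `scan` (window table), `regions` (all criteria combined),
#'   `region_genes`, `sweep_gene_ids` (unique genes under any criterion).
#' @export
run_sweep_scan <- function(vs, gm, window = 150000L, step = 75000L,
                           chrom_lengths = NULL, min_snps = 10L,
                           top_frac = 0.01) {
  scan <- sweep_scan(vs, window, step, chrom_lengths, min_snps)
  parts <- list(
    merge_regions(select_extreme_windows(scan, "z_fst_high",
                                         top_frac = top_frac)),
    merge_regions(select_extreme_windows(scan, "z_hp_low", "A", top_frac)),
    merge_regions(select_extreme_windows(scan, "z_hp_low", "B", top_frac)))
  regions <- data.table::rbindlist(parts)
  gr <- genes_in_regions(regions, gm)
  list(scan = scan, regions = gr$regions, region_genes = gr$region_genes,
       sweep_gene_ids = sort(unique(gr$region_genes$gene_id)))
}
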