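# Independent oracles.  These deliberately re-derive each statistic by the
# most direct route available (enumeration, scalar arithmetic, stats::
# reference implementations) and are never shared with package code.

# Two-sided exact binomial p against 0.5 by exhaustive enumeration:
# sum of P(X = x) over all outcomes no more likely than the observed one.
oracle_binom_two_sided <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-9)])
}

# BH step-up via the reference implementation in stats.
oracle_bh <- function(p) stats::p.adjust(p, method = "BH")

# Weir & Cockerham (1984) variance components for a single biallelic site,
# two populations, written scalar-by-scalar from the published formulas.
oracle_wc_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2); r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# Exhaustive per-site strict discriminating check (the definition, looped).
oracle_strict_discriminating <- function(ga, gb) {
  ga_ok <- ga[!is.na(ga)]; gb_ok <- gb[!is.na(gb)]
  if (!length(ga_ok) || !length(gb_ok)) return(FALSE)
  if (any(is.na(ga)) || any(is.na(gb))) return(FALSE)  # max_missing_frac = 0
  if (!all(ga_ok %in% c(0, 2)) || !all(gb_ok %in% c(0, 2))) return(FALSE)
  a_allele <- unique(ga_ok); b_allele <- unique(gb_ok)
  length(a_allele) == 1 && length(b_allele) == 1 && a_allele != b_allele
}
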