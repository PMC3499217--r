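# Independent oracles used across the suite.  These deliberately take
# different computational routes from the package implementations.

# Dirichlet(1/2, 1/2) posterior-predictive probability of a genotype with
# dosage g given n_alt of n_obs reference alleles, via the closed-form
# beta-function ratio (integral over the posterior) rather than the
# sequential Polya-urn product used by the package.
polya_oracle <- function(g, n_alt, n_obs) {
  n_ref <- n_obs - n_alt
  choose(2, g) * exp(lbeta(n_alt + 0.5 + g, n_ref + 0.5 + (2 - g)) -
                     lbeta(n_alt + 0.5, n_ref + 0.5))
}

# Weir & Cockerham (1984) theta for one locus and two populations via the
# ANOVA mean-squares route (MSP/MSI/MSG), independent of the package's
# direct variance-component formulas.  g1, g2: dosage vectors (no NA).
wc_anova_oracle <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2); n_tot <- n1 + n2
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  p_all <- (n1 * p1 + n2 * p2) / n_tot
  SSP <- 2 * n1 * (p1 - p_all)^2 + 2 * n2 * (p2 - p_all)^2
  SSI <- sum(2 * (g1 / 2 - p1)^2) + sum(2 * (g2 / 2 - p2)^2)
  SSG <- 0.5 * (sum(g1 == 1) + sum(g2 == 1))
  MSP <- SSP / 1
  MSI <- SSI / (n_tot - 2)
  MSG <- SSG / n_tot
  n_c <- (n_tot - (n1^2 + n2^2) / n_tot) / 1
  a <- (MSP - MSI) / (2 * n_c)
  b <- (MSI - MSG) / 2
  c_ <- MSG
  list(a = a, b = b, c = c_,
       theta = if (a + b + c_ == 0) NA_real_ else a / (a + b + c_))
}

# r^2 from phased haplotype counts (AB, Ab, aB, ab).
r2_from_haplotypes <- function(h) {
  f <- h / sum(h)
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  D <- f[1] - pA * pB
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# Least-squares fit of a 4-taxon unrooted topology to a distance matrix.
# Topologies indexed by the taxon paired with taxon 1: 2, 3 or 4.
fit_quartet <- function(d, mate) {
  taxa <- 1:4
  others <- setdiff(taxa, c(1, mate))
  # edges: e1..e4 pendant for taxa 1..4, e5 internal
  pairs <- utils::combn(4, 2)
  A <- matrix(0, 6, 5)
  y <- numeric(6)
  for (k in 1:6) {
    i <- pairs[1, k]; j <- pairs[2, k]
    A[k, i] <- 1; A[k, j] <- 1
    same_side <- (i %in% c(1, mate)) == (j %in% c(1, mate))
    if (!same_side) A[k, 5] <- 1
    y[k] <- d[i, j]
  }
  fit <- qr.solve(crossprod(A), crossprod(A, y))
  list(edges = fit, rss = sum((A %*% fit - y)^2))
}

best_quartet_topology <- function(d) {
  rss <- vapply(2:4, function(m) fit_quartet(d, m)$rss, numeric(1))
  c(2, 3, 4)[which.min(rss)]
}

# Which taxon (by alphabetical index) is taxon 1's cherry-mate in an
# unrooted 4-taxon phylo tree.  The bipartition keys are normalized to the
# side not containing the first alphabetical label, i.e. the non-mate pair.
quartet_mate <- function(tree) {
  stopifnot(length(tree$tip.label) == 4)
  labels <- sort(tree$tip.label)
  keys <- breedassign:::tree_bipartitions(tree)
  for (m in 2:4) {
    split <- paste(labels[setdiff(1:4, c(1, m))], collapse = "|")
    if (split %in% keys) return(m)
  }
  stop("no cherry found")
}

# Tiny deterministic dataset builder.
toy_dataset <- function(calls, breed, ...) {
  genotype_dataset(matrix(as.integer(calls), nrow = length(breed),
                          byrow = TRUE), breed, ...)
}
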