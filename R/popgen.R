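# Population-differentiation statistics.

# Per-locus summaries needed by the variance-component estimator: sample
# sizes (genotyped individuals), alt-allele frequencies, observed
# heterozygote frequencies.
locus_pop_summary <- function(calls) {
  n <- colSums(!is.na(calls))
  p <- ifelse(n > 0, colSums(calls, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(calls == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Weir & Cockerham's multi-locus theta between two breeds
#'
#' The 1984 variance-component estimator of Wright's fixation index for two
#' populations: per locus the among-population (a), among-individual (b) and
#' within-individual (c) components are computed from sample sizes, allele
#' frequencies and observed heterozygosities; the multi-locus estimate is
#' the ratio of sums, `sum(a) / sum(a + b + c)` (the standard aggregation;
#' monomorphic loci contribute zero to both sums).  Missing genotypes reduce
#' the per-locus sample sizes; loci with fewer than two genotyped
#' individuals in either breed are skipped.
#'
#' @param data a [genotype_dataset()].
#' @param breed_A,breed_B breed labels (each needs >= 2 samples).
#' @return theta (may be slightly negative); `NA` when no locus is usable or
#'   all loci are monomorphic.  Attribute `loci_used` records the count.
#' @export
wc_fst <- function(data, breed_A, breed_B) {
  for (b in c(breed_A, breed_B)) {
    if (!b %in% data$breed) stop_val("unknown breed: ", b)
    if (sum(data$breed == b) < 2L) stop_val("breed ", b, " needs >= 2 samples")
  }
  comp <- wc_components(data$calls[data$breed == breed_A, , drop = FALSE],
                        data$calls[data$breed == breed_B, , drop = FALSE])
  denom <- sum(comp$a + comp$b + comp$c)
  theta <- if (length(comp$a) == 0L || denom == 0) NA_real_ else
    sum(comp$a) / denom
  structure(theta, loci_used = length(comp$a))
}

# Per-locus a, b, c components (Weir & Cockerham 1984, r = 2 populations).
wc_components <- function(calls_1, calls_2) {
  s1 <- locus_pop_summary(calls_1)
  s2 <- locus_pop_summary(calls_2)
  ok <- which(s1$n >= 2L & s2$n >= 2L)
  n1 <- s1$n[ok]; n2 <- s2$n[ok]
  p1 <- s1$p[ok]; p2 <- s2$p[ok]
  h1 <- s1$h[ok]; h2 <- s2$h[ok]
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2v <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2v - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2v - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2v -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  c_ <- h_bar / 2
  list(a = a, b = b, c = c_)
}

pairwise_matrix <- function(data, breeds_use, fun, kind) {
  brd <- breeds_use %||% breeds(data)
  if (length(brd) < 2L) stop_val("need at least two breeds")
  B <- length(brd)
  m <- matrix(0, B, B, dimnames = list(brd, brd))
  for (i in seq_len(B - 1L)) for (j in (i + 1L):B) {
    v <- fun(brd[i], brd[j])
    m[i, j] <- m[j, i] <- v
  }
  off <- m; diag(off) <- NA
  breed_means <- data.frame(
    breed = brd,
    mean = rowMeans(off, na.rm = TRUE),
    sd = apply(off, 1L, sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(kind = kind, values = m, breed_means = breed_means),
            class = "pairwise_stat_matrix")
}

#' Pairwise Weir-Cockerham F_ST matrix with per-breed means
#'
#' @param data a [genotype_dataset()].
#' @param breeds_use optional subset of breed labels.
#' @return a `pairwise_stat_matrix`: symmetric `values` matrix (diagonal 0)
#'   and a `breed_means` table (mean and SD of each breed's off-diagonal
#'   row -- the "average breed F_ST" column of a differentiation table).
#' @export
fst_matrix <- function(data, breeds_use = NULL) {
  pairwise_matrix(data, breeds_use,
                  function(a, b) as.numeric(wc_fst(data, a, b)), "wc_fst")
}

#' Pairwise Reynolds coancestry distance matrix
#'
#' The frequency-based Reynolds, Weir & Cockerham (1983) distance in its
#' gendist-style aggregation: per locus the numerator is
#' `sum_a (p1a - p2a)^2 / 2` and the denominator `1 - sum_a p1a p2a`; the
#' distance is the locus-summed numerator over the locus-summed denominator
#' (no `-ln(1 - theta)` transform).  Loci with an undefined frequency in
#' either breed are skipped.
#'
#' @inheritParams fst_matrix
#' @return a `pairwise_stat_matrix` of kind `"reynolds"`.
#' @export
reynolds_matrix <- function(data, breeds_use = NULL) {
  bc <- breed_counts(data)
  fr <- bc$freq
  pairwise_matrix(data, breeds_use, function(a, b) {
    reynolds_from_freqs(fr[a, ], fr[b, ])
  }, "reynolds")
}

reynolds_from_freqs <- function(p1, p2) {
  ok <- !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  num <- (p1 - p2)^2                     # = sum over both alleles of diff^2/2
  den <- 1 - (p1 * p2 + (1 - p1) * (1 - p2))
  if (sum(den) == 0) return(NA_real_)
  sum(num) / sum(den)
}

#' @export
print.pairwise_stat_matrix <- function(x, ...) {
  cat("pairwise_stat_matrix (", x$kind, "): ", nrow(x$values),
      " breeds\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}
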