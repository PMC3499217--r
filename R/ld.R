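#' EM-based r-squared linkage disequilibrium between two loci
#'
#' Two-locus haplotype frequencies are estimated from unphased genotypes of
#' one breed by expectation-maximisation (only the double heterozygote has
#' ambiguous phase); `r^2 = D^2 / (p(1-p) q(1-q))` with
#' `D = f(AB) - p q`.  Convergence: |change in log-likelihood| < 1e-8, at
#' most 1000 iterations.  A monomorphic locus yields the undefined sentinel
#' (`NA`).
#'
#' @param data a [genotype_dataset()].
#' @param breed breed label.
#' @param locus_i,locus_j locus ids.
#' @return an `ld_result` list: `locus_i`, `locus_j`, `breed`, `r_squared`
#'   (`NA` if undefined), `D`, `haplotype_freqs` (AB, Ab, aB, ab where A/B
#'   denote the alt alleles), `em_converged`, `n_iter`, `n_used`.
#' @export
r2_pair <- function(data, breed, locus_i, locus_j) {
  if (!breed %in% data$breed) stop_val("unknown breed: ", breed)
  for (l in c(locus_i, locus_j))
    if (!l %in% colnames(data$calls)) stop_val("unknown locus: ", l)
  rows <- data$breed == breed
  gA <- data$calls[rows, locus_i]
  gB <- data$calls[rows, locus_j]
  ok <- !is.na(gA) & !is.na(gB)
  gA <- gA[ok]; gB <- gB[ok]
  res <- list(locus_i = locus_i, locus_j = locus_j, breed = breed,
              r_squared = NA_real_, D = NA_real_,
              haplotype_freqs = c(AB = NA, Ab = NA, aB = NA, ab = NA),
              em_converged = TRUE, n_iter = 0L, n_used = length(gA))
  class(res) <- "ld_result"
  if (length(gA) == 0L) return(res)
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(res)  # monomorphic
  n_hap <- 2L * length(gA)
  # fixed haplotype contributions; the double het splits between AB/ab and
  # Ab/aB phases in the E-step
  n_dh <- sum(gA == 1L & gB == 1L)
  # count unambiguous haplotypes directly: each individual carries two
  # haplotypes; for all genotype combos except (1,1) the split is unique
  cnt <- function(a, b) sum(gA == a & gB == b)
  base <- c(
    AB = 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2),
    Ab = 2 * cnt(2, 0) + cnt(2, 1) + cnt(1, 0),
    aB = 2 * cnt(0, 2) + cnt(0, 1) + cnt(1, 2),
    ab = 2 * cnt(0, 0) + cnt(0, 1) + cnt(1, 0))
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  loglik <- function(f) {
    p_dh <- 2 * f["AB"] * f["ab"] + 2 * f["Ab"] * f["aB"]
    sum(base * log(pmax(f, 1e-300))) + n_dh * log(max(p_dh, 1e-300))
  }
  ll_old <- loglik(f)
  converged <- FALSE
  it <- 0L
  while (it < 1000L) {
    it <- it + 1L
    p_cis <- 2 * f["AB"] * f["ab"]
    p_trans <- 2 * f["Ab"] * f["aB"]
    w <- if (p_cis + p_trans > 0) p_cis / (p_cis + p_trans) else 0.5
    e <- base + n_dh * c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
    f <- e / n_hap
    ll_new <- loglik(f)
    if (abs(ll_new - ll_old) < 1e-8) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  D <- f[["AB"]] - pA * pB
  res$r_squared <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  res$D <- D
  res$haplotype_freqs <- f
  res$em_converged <- converged
  res$n_iter <- it
  res
}
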