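# Partial-Bayesian (Rannala-Mountain) assignment machinery.
#
# A query genotype is scored against a reference breed by the predictive
# probability of drawing its two alleles as additional draws from the
# Dirichlet posterior on that breed's allele frequencies (uniform prior 1/k
# per allele, k = 2 for SNPs).  With n_a alt alleles observed out of n:
#   P(hom alt)  = ((n_a + 1/2)/(n + 1)) * ((n_a + 3/2)/(n + 2))
#   P(het)      = 2 ((n_a + 1/2)/(n + 1)) * ((n - n_a + 1/2)/(n + 2))
#   P(hom ref)  = ((n - n_a + 1/2)/(n + 1)) * ((n - n_a + 3/2)/(n + 2))
# These sum to one for any counts and stay strictly positive even for
# alleles never observed in the reference, so log-likelihoods are finite.

# L x 3 matrix of log10 genotype probabilities (columns: dosage 0, 1, 2).
rm_log10_probs <- function(n_alt, n_obs) {
  n_ref <- n_obs - n_alt
  p0 <- ((n_ref + 0.5) / (n_obs + 1)) * ((n_ref + 1.5) / (n_obs + 2))
  p1 <- 2 * ((n_alt + 0.5) / (n_obs + 1)) * ((n_ref + 0.5) / (n_obs + 2))
  p2 <- ((n_alt + 0.5) / (n_obs + 1)) * ((n_alt + 1.5) / (n_obs + 2))
  log10(cbind(`0` = p0, `1` = p1, `2` = p2))
}

#' Rannala-Mountain log10 likelihood of a multilocus genotype
#'
#' Per non-missing locus, the probability of the individual's two alleles as
#' sequential draws from the Dirichlet-posterior predictive given the
#' reference allele counts (uniform 1/2 prior per allele); the returned value
#' is the log10 of the product over loci.  Missing loci are skipped
#' (marginalised), never penalised.
#'
#' @param genotype integer vector of alt-allele dosages (0/1/2, `NA` =
#'   missing), aligned with the rows of `counts`.
#' @param counts an [estimate_frequencies()] table (needs `n_alt`, `n_obs`).
#' @return a finite log10 likelihood (0 loci scored gives 0).
#' @export
genotype_log_likelihood <- function(genotype, counts) {
  stopifnot(length(genotype) == nrow(counts))
  obs <- which(!is.na(genotype))
  if (!length(obs)) return(0)
  lp <- rm_log10_probs(counts$n_alt[obs], counts$n_obs[obs])
  sum(lp[cbind(seq_along(obs), genotype[obs] + 1L)])
}

# Log10 likelihood matrix (samples x breeds) for a genotype matrix G against
# per-breed count matrices; all counts as observed (no leave-one-out).
loglik_matrix <- function(G, bc) {
  n <- nrow(G); B <- length(bc$breeds)
  I0 <- (!is.na(G) & G == 0L) + 0
  I1 <- (!is.na(G) & G == 1L) + 0
  I2 <- (!is.na(G) & G == 2L) + 0
  LL <- matrix(NA_real_, n, B, dimnames = list(rownames(G), bc$breeds))
  for (b in seq_len(B)) {
    lp <- rm_log10_probs(bc$n_alt[b, ], bc$n_obs[b, ])
    LL[, b] <- I0 %*% lp[, 1L] + I1 %*% lp[, 2L] + I2 %*% lp[, 3L]
  }
  LL
}

# Leave-one-out log10 likelihood of each reference sample in its own breed.
loo_own_loglik <- function(G, bc, breed_of) {
  n <- nrow(G)
  out <- numeric(n)
  bidx <- match(breed_of, bc$breeds)
  for (i in seq_len(n)) {
    g <- G[i, ]
    obs <- which(!is.na(g))
    if (!length(obs)) { out[i] <- 0; next }
    b <- bidx[i]
    n_alt <- bc$n_alt[b, obs] - g[obs]
    n_obs <- bc$n_obs[b, obs] - 2L
    lp <- rm_log10_probs(n_alt, n_obs)
    out[i] <- sum(lp[cbind(seq_along(obs), g[obs] + 1L)])
  }
  out
}

#' Leave-one-out self-assignment of every reference individual
#'
#' Each individual is scored in every reference breed; for its own breed the
#' allele counts are first re-estimated excluding that individual
#' (leave-one-out), so reference members do not inflate their own
#' likelihood.  The individual is assigned to the breed with the highest
#' log10 likelihood; exact ties go to the lexicographically first tied breed
#' and are flagged in the result.
#'
#' @param data a [genotype_dataset()].
#' @param panel optional [select_panel()] result or locus-id vector;
#'   `NULL` = all loci.
#' @return an `assignment_result` `data.frame`: `sample_id`, `true_breed`,
#'   `assigned_breed`, `correct`, `n_loci_used`, `tied`, then one
#'   `loglik_<breed>` column per breed.
#' @export
self_assign_all <- function(data, panel = NULL) {
  ids <- resolve_panel(data, panel)
  G <- data$calls[, ids, drop = FALSE]
  bc <- breed_counts(data, ids)
  singletons <- names(which(table(data$breed) == 1L))
  if (length(singletons))
    warning("breed(s) with a single sample (leave-one-out empties the ",
            "reference; prior-only likelihood used): ",
            paste(singletons, collapse = ", "))
  LL <- loglik_matrix(G, bc)
  own <- loo_own_loglik(G, bc, data$breed)
  LL[cbind(seq_len(nrow(G)), match(data$breed, bc$breeds))] <- own
  best <- apply(LL, 1L, max)
  tied <- rowSums(LL == best) > 1L
  assigned <- bc$breeds[apply(LL, 1L, which.max)]  # first max = lexicographic
  out <- data.frame(sample_id = rownames(G), true_breed = unname(data$breed),
                    assigned_breed = assigned,
                    correct = assigned == unname(data$breed),
                    n_loci_used = rowSums(!is.na(G)), tied = unname(tied),
                    row.names = NULL, stringsAsFactors = FALSE)
  ll <- as.data.frame(LL)
  names(ll) <- paste0("loglik_", bc$breeds)
  structure(cbind(out, ll, stringsAsFactors = FALSE),
            class = c("assignment_result", "data.frame"))
}

#' Exclusion-test configuration
#'
#' @param n_sim simulated genotypes per reference breed (default 10000).
#' @param alpha critical rejection region in (0, 1) (default 0.001): a query
#'   is excluded from a breed when its likelihood falls strictly below the
#'   `ceiling(alpha * n_sim)`-th lowest simulated likelihood.
#' @param seed master seed for the simulation streams.
#' @return an `exclusion_config` list.
#' @export
exclusion_config <- function(n_sim = 10000L, alpha = 0.001, seed = 1L) {
  stopifnot(n_sim >= 1)
  assert_fraction(alpha, "alpha")
  k <- ceiling(alpha * n_sim)
  if (k < 1 || k > n_sim)
    stop_val("need 1 <= ceiling(alpha * n_sim) <= n_sim")
  structure(list(n_sim = as.integer(n_sim), alpha = alpha,
                 seed = as.integer(seed)), class = "exclusion_config")
}

#' Exclusion-simulation test against every reference breed
#'
#' For each reference breed, `n_sim` multilocus genotypes are simulated
#' locus-independently under Hardy-Weinberg from the breed's observed allele
#' frequencies and scored against the breed's counts; the critical value is
#' the `ceiling(alpha * n_sim)`-th lowest simulated log10 likelihood.  A
#' query is excluded from a breed iff its likelihood is strictly below the
#' critical value (leave-one-out counts are used when the query belongs to
#' that breed's reference).  Unlike self-assignment, a query can be excluded
#' from every reference population -- the signature of an unsampled origin.
#'
#' @param data the reference [genotype_dataset()].
#' @param panel optional panel restriction (as in [self_assign_all()]).
#' @param cfg an [exclusion_config()].
#' @param queries optional second [genotype_dataset()] of external query
#'   individuals (same loci); they are scored against the full reference
#'   counts and their breed labels are treated as claimed origins.  When
#'   `NULL` the reference individuals themselves are tested.
#' @return an `exclusion_result` list: `records` (`sample_id`, `true_breed`,
#'   `excluded_from_true`, `excluded_from_all`, `n_loci_used`), `loglik` and
#'   `excluded` matrices (samples x breeds), and `critical_values`.
#' @export
exclusion_test <- function(data, panel = NULL, cfg = exclusion_config(),
                           queries = NULL) {
  stopifnot(inherits(cfg, "exclusion_config"))
  ids <- resolve_panel(data, panel)
  bc <- breed_counts(data, ids)
  freq <- bc$freq
  if (anyNA(freq)) {
    warning("breed frequency undefined at ", sum(is.na(freq)),
            " breed-locus cells; prior-mean 0.5 used for null simulation")
    freq[is.na(freq)] <- 0.5
  }
  B <- length(bc$breeds)
  k <- ceiling(cfg$alpha * cfg$n_sim)
  crit <- setNames(numeric(B), bc$breeds)
  for (b in seq_len(B)) {
    sims <- withr::with_seed(derive_seed(cfg$seed, "exclusion") + b, {
      matrix(rbinom(cfg$n_sim * length(ids), 2L,
                    rep(freq[b, ], each = cfg$n_sim)),
             cfg$n_sim, length(ids))
    })
    lp <- rm_log10_probs(bc$n_alt[b, ], bc$n_obs[b, ])
    ll <- (sims == 0L) %*% lp[, 1L] + (sims == 1L) %*% lp[, 2L] +
      (sims == 2L) %*% lp[, 3L]
    crit[b] <- sort(ll, partial = k)[k]
  }
  if (is.null(queries)) {
    G <- data$calls[, ids, drop = FALSE]
    labels <- unname(data$breed)
    LL <- loglik_matrix(G, bc)
    own <- loo_own_loglik(G, bc, data$breed)
    LL[cbind(seq_len(nrow(G)), match(data$breed, bc$breeds))] <- own
  } else {
    stopifnot(inherits(queries, "genotype_dataset"))
    G <- queries$calls[, ids, drop = FALSE]
    labels <- unname(queries$breed)
    LL <- loglik_matrix(G, bc)
  }
  excluded <- sweep(LL, 2L, crit, `<`)
  tb <- match(labels, bc$breeds)
  from_true <- ifelse(is.na(tb), NA,
                      excluded[cbind(seq_len(nrow(G)), tb)])
  structure(list(
    records = data.frame(sample_id = rownames(G), true_breed = labels,
                         excluded_from_true = from_true,
                         excluded_from_all = rowSums(excluded) == ncol(excluded),
                         n_loci_used = rowSums(!is.na(G)),
                         row.names = NULL, stringsAsFactors = FALSE),
    loglik = LL, excluded = excluded, critical_values = crit,
    config = cfg), class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  r <- x$records
  cat("exclusion_result:", nrow(r), "queries;",
      sum(r$excluded_from_true, na.rm = TRUE), "excluded from true/claimed",
      "breed;", sum(r$excluded_from_all), "excluded from all breeds\n")
  invisible(x)
}
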