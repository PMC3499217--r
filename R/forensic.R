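# Pairwise breed-contrast power analysis.
#
# For a claimed breed A against an alternative breed B, each reference
# individual contributes log(LR) = log10 L(A) - log10 L(B) (leave-one-out in
# its own breed).  The observed log(LR) distributions are summarised by mean
# and SD; tail rates at a test threshold t come from a normal approximation
# (the only way the minute false-positive rates behind near-unity posteriors
# are resolvable from ~30 animals), with an empirical-counting fallback for
# diagnostics.  The posterior probability that a positive test reflects true
# claimed origin, with equal priors, is ((1-b)/a) / ((1-b)/a + 1).

#' Pairwise log-likelihood-ratio distributions for a breed contrast
#'
#' @param data a [genotype_dataset()].
#' @param panel optional panel restriction.
#' @param breed_A claimed breed; `breed_B` alternative breed (distinct, both
#'   with at least two samples).
#' @param breed_B see `breed_A`.
#' @return a `contrast_distributions` list: `loglr_A`, `loglr_B` (log(LR)
#'   values for individuals of true origin A resp. B), their means and SDs.
#' @export
pairwise_loglr <- function(data, panel = NULL, breed_A, breed_B) {
  if (identical(breed_A, breed_B))
    stop_val("breed_A and breed_B must differ")
  for (b in c(breed_A, breed_B)) {
    if (!b %in% data$breed) stop_val("unknown breed: ", b)
    if (sum(data$breed == b) < 2L)
      stop_val("breed ", b, " has fewer than 2 samples (SD undefined)")
  }
  ids <- resolve_panel(data, panel)
  G <- data$calls[, ids, drop = FALSE]
  bc <- breed_counts(data, ids)
  LL <- loglik_matrix(G, bc)
  own <- loo_own_loglik(G, bc, data$breed)
  iA <- which(data$breed == breed_A)
  iB <- which(data$breed == breed_B)
  ja <- match(breed_A, bc$breeds); jb <- match(breed_B, bc$breeds)
  loglr_A <- own[iA] - LL[iA, jb]
  loglr_B <- LL[iB, ja] - own[iB]
  structure(list(breed_A = breed_A, breed_B = breed_B,
                 loglr_A = unname(loglr_A), loglr_B = unname(loglr_B),
                 mean_A = mean(loglr_A), sd_A = sd(loglr_A),
                 mean_B = mean(loglr_B), sd_B = sd(loglr_B)),
            class = "contrast_distributions")
}

#' False-positive and true-positive rates of a log(LR) test
#'
#' @param dist a [pairwise_loglr()] result.
#' @param threshold the test value t in "log(LR) > t".
#' @param method `"normal"` (default; rates from the normal approximation to
#'   the observed log(LR) distributions) or `"empirical"` (exceedance
#'   counting; cannot resolve rates below 1/n).
#' @param alpha_floor lower bound applied to the false-positive rate before
#'   forming posterior odds (default 1e-12).
#' @return a `contrast_error_rates` list: `threshold`, `alpha_fp`, `tp`,
#'   `alpha_raw` (pre-floor value).
#' @export
contrast_error_rates <- function(dist, threshold,
                                 method = c("normal", "empirical"),
                                 alpha_floor = 1e-12) {
  stopifnot(inherits(dist, "contrast_distributions"))
  method <- match.arg(method)
  if (method == "normal") {
    if (!is.finite(dist$sd_A) || !is.finite(dist$sd_B) ||
        dist$sd_A == 0 || dist$sd_B == 0)
      stop_val("zero/undefined log(LR) SD; use method = \"empirical\"")
    alpha_raw <- pnorm((threshold - dist$mean_B) / dist$sd_B,
                       lower.tail = FALSE)
    tp <- pnorm((threshold - dist$mean_A) / dist$sd_A, lower.tail = FALSE)
  } else {
    alpha_raw <- mean(dist$loglr_B > threshold)
    tp <- mean(dist$loglr_A > threshold)
  }
  structure(list(threshold = threshold, alpha_fp = max(alpha_raw, alpha_floor),
                 tp = tp, alpha_raw = alpha_raw, method = method),
            class = "contrast_error_rates")
}

#' Posterior probability of correct breed assignment
#'
#' With equal prior odds, the posterior that a positive test (log(LR) above
#' threshold) reflects true claimed origin is `odds / (odds + 1)` where
#' `odds = tp / alpha_fp`.
#'
#' @param rates a [contrast_error_rates()] result.
#' @return posterior probability in \[0, 1\].
#' @export
posterior_correct_assignment <- function(rates) {
  stopifnot(inherits(rates, "contrast_error_rates"))
  if (rates$tp == 0 && rates$alpha_raw == 0)
    stop_val("tp and alpha_fp both zero: posterior undefined")
  odds <- rates$tp / rates$alpha_fp
  odds / (odds + 1)
}

#' Posterior matrix over all ordered breed contrasts
#'
#' Fills every ordered (claimed, contrasted) breed pair at every threshold
#' with the posterior probability of correct assignment, rounded to 6
#' decimals; the diagonal is empty.  Entries printed as 1 are a rounding
#' convention, not literal unity (the false-positive rate is floored, never
#' exactly zero).
#'
#' @inheritParams pairwise_loglr
#' @param thresholds numeric test values (default `c(0, 2)`).
#' @param method passed to [contrast_error_rates()].
#' @return a `posterior_matrix`: named list of breeds x breeds matrices
#'   (claimed in rows), one per threshold.
#' @export
contrast_matrix <- function(data, panel = NULL, thresholds = c(0, 2),
                            method = c("normal", "empirical")) {
  method <- match.arg(method)
  brd <- breeds(data)
  if (length(brd) < 2L) stop_val("need at least two breeds")
  small <- brd[vapply(brd, function(b) sum(data$breed == b) < 2L, logical(1))]
  if (length(small))
    stop_val("breed(s) with fewer than 2 samples: ",
             paste(small, collapse = ", "))
  ids <- resolve_panel(data, panel)
  G <- data$calls[, ids, drop = FALSE]
  bc <- breed_counts(data, ids)
  LL <- loglik_matrix(G, bc)
  own <- loo_own_loglik(G, bc, data$breed)
  B <- length(brd)
  out <- lapply(thresholds, function(t)
    matrix(NA_real_, B, B, dimnames = list(claimed = brd, contrasted = brd)))
  names(out) <- paste0("t", thresholds)
  for (a in seq_len(B)) for (b in seq_len(B)) {
    if (a == b) next
    iA <- which(data$breed == brd[a]); iB <- which(data$breed == brd[b])
    dist <- structure(list(breed_A = brd[a], breed_B = brd[b],
                           loglr_A = own[iA] - LL[iA, b],
                           loglr_B = LL[iB, a] - own[iB]),
                      class = "contrast_distributions")
    dist$mean_A <- mean(dist$loglr_A); dist$sd_A <- sd(dist$loglr_A)
    dist$mean_B <- mean(dist$loglr_B); dist$sd_B <- sd(dist$loglr_B)
    for (k in seq_along(thresholds)) {
      r <- contrast_error_rates(dist, thresholds[k], method = method)
      out[[k]][a, b] <- round(posterior_correct_assignment(r), 6L)
    }
  }
  structure(out, class = "posterior_matrix")
}
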