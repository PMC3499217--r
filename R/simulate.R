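#' Simulation scenario for breed-structured genotype data
#'
#' Describes a Balding-Nichols world: per locus an ancestral frequency is
#' drawn uniformly, and each breed's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with its divergence parameter `F`.  A
#' "close pair" shares an intermediate ancestor: the intermediate frequency is
#' drawn once with the pair's shared `F`, then each member is drawn from it
#' with a much smaller `F_pair` -- mimicking a recently split breed pair.
#' Loci are unlinked; an optional correlated-pair generator copies loci with
#' a per-allele resampling error to create controlled LD for screening tests.
#'
#' @param n_breeds integer >= 2.
#' @param samples_per_breed integer vector (recycled to `n_breeds`).
#' @param n_loci integer >= 1.
#' @param breed_F per-breed divergence parameter in (0, 1) (recycled).
#' @param ancestral_freq_range interval within (0, 1); default `c(0.05, 0.95)`.
#' @param close_pairs list of specs: `list(members = c(i, j), F_pair = ...,
#'   F_shared = ...)`; members by index or breed name; `F_shared` defaults to
#'   the mean of the members' `breed_F`.
#' @param missing_rate per-call missingness probability in \[0, 0.5\].
#' @param admix_fraction fraction of individuals drawn as two-breed mixtures.
#' @param admix_m mixing proportion in (0, 1): each allele copies from the
#'   labelled breed with probability `admix_m`, else from a random partner.
#' @param n_ld_pairs number of correlated locus pairs to inject.
#' @param ld_copy_error per-allele resampling probability for the copied
#'   member of each correlated pair (0 = perfect LD).
#' @param breed_names optional character vector of labels.
#' @param seed master seed; all stages derive child seeds from it.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(n_breeds, samples_per_breed, n_loci, breed_F,
                         ancestral_freq_range = c(0.05, 0.95),
                         close_pairs = list(), missing_rate = 0,
                         admix_fraction = 0, admix_m = 0.5,
                         n_ld_pairs = 0L, ld_copy_error = 0.02,
                         breed_names = NULL, seed = 1L) {
  stopifnot(n_breeds >= 2, n_loci >= 1)
  samples_per_breed <- rep_len(as.integer(samples_per_breed), n_breeds)
  stopifnot(all(samples_per_breed >= 1))
  breed_F <- rep_len(breed_F, n_breeds)
  if (any(breed_F <= 0 | breed_F >= 1))
    stop_val("breed_F values must lie in (0, 1)")
  assert_fraction(missing_rate, "missing_rate", 0, 0.5)
  assert_fraction(admix_fraction, "admix_fraction")
  stopifnot(length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  if (is.null(breed_names))
    breed_names <- sprintf("B%02d", seq_len(n_breeds))
  stopifnot(length(breed_names) == n_breeds, !anyDuplicated(breed_names))
  close_pairs <- lapply(close_pairs, function(cp) {
    m <- cp$members
    if (is.character(m)) m <- match(m, breed_names)
    if (length(m) != 2L || anyNA(m) || any(m < 1 | m > n_breeds))
      stop_val("close_pairs members must name two distinct breeds")
    cp$members <- as.integer(m)
    if (is.null(cp$F_pair) || cp$F_pair <= 0 || cp$F_pair >= 1)
      stop_val("close_pairs need F_pair in (0, 1)")
    cp$F_shared <- cp$F_shared %||% mean(breed_F[m])
    cp
  })
  structure(list(n_breeds = as.integer(n_breeds),
                 samples_per_breed = samples_per_breed,
                 n_loci = as.integer(n_loci), breed_F = breed_F,
                 ancestral_freq_range = ancestral_freq_range,
                 close_pairs = close_pairs, missing_rate = missing_rate,
                 admix_fraction = admix_fraction, admix_m = admix_m,
                 n_ld_pairs = as.integer(n_ld_pairs),
                 ld_copy_error = ld_copy_error,
                 breed_names = breed_names, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Draw true per-breed allele frequencies under the Balding-Nichols model
#'
#' @param scenario a [sim_scenario()].
#' @return a `breed_freqs` matrix (breeds x loci) of true alternate-allele
#'   frequencies, with the scenario attached as an attribute.
#' @export
simulate_breed_frequencies <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  s <- scenario
  withr::with_seed(derive_seed(s$seed, "frequencies"), {
    L <- s$n_loci
    p_anc <- runif(L, s$ancestral_freq_range[1], s$ancestral_freq_range[2])
    bn_draw <- function(p, f) rbeta(length(p), p * (1 - f) / f,
                                    (1 - p) * (1 - f) / f)
    pair_member <- integer(0)
    intermediates <- list()
    for (k in seq_along(s$close_pairs)) {
      cp <- s$close_pairs[[k]]
      intermediates[[k]] <- bn_draw(p_anc, cp$F_shared)
      pair_member[as.character(cp$members)] <- k
    }
    freqs <- matrix(NA_real_, s$n_breeds, L,
                    dimnames = list(s$breed_names,
                                    sprintf("L%04d", seq_len(L))))
    for (b in seq_len(s$n_breeds)) {
      k <- pair_member[as.character(b)]
      freqs[b, ] <- if (!is.na(k) && length(k))
        bn_draw(intermediates[[k]], s$close_pairs[[k]]$F_pair)
      else bn_draw(p_anc, s$breed_F[b])
    }
    structure(freqs, scenario = s, class = c("breed_freqs", "matrix"))
  })
}

#' Simulate diploid genotypes from true breed frequencies
#'
#' Genotypes are drawn binomial(2, p) per locus (Hardy-Weinberg within
#' breed).  Admixed individuals (if any) draw each allele copy from the
#' labelled breed with probability `admix_m` and from a uniformly chosen
#' partner breed otherwise; they keep the labelled breed.  Missing calls are
#' masked independently at `missing_rate`.  Correlated locus pairs, when
#' requested, overwrite the pair's second locus with a noisy copy of the
#' first and co-locate it on the map.
#'
#' @param freqs a `breed_freqs` matrix from [simulate_breed_frequencies()].
#' @param scenario the generating [sim_scenario()]; defaults to the one
#'   attached to `freqs`.
#' @return a [genotype_dataset()].  Simulated loci are mapped round-robin to
#'   chromosomes 1..18 at a 40-kb spacing, echoing a dense genome-wide chip.
#' @export
simulate_genotypes <- function(freqs, scenario = attr(freqs, "scenario")) {
  stopifnot(inherits(scenario, "sim_scenario"))
  s <- scenario
  stopifnot(nrow(freqs) == s$n_breeds, ncol(freqs) == s$n_loci)
  withr::with_seed(derive_seed(s$seed, "genotypes"), {
    L <- s$n_loci
    n_tot <- sum(s$samples_per_breed)
    calls <- matrix(NA_integer_, n_tot, L)
    labels <- rep(s$breed_names, s$samples_per_breed)
    row <- 0L
    for (b in seq_len(s$n_breeds)) {
      nb <- s$samples_per_breed[b]
      g <- matrix(rbinom(nb * L, 2L, rep(freqs[b, ], each = nb)), nb, L)
      calls[row + seq_len(nb), ] <- g
      row <- row + nb
    }
    if (s$admix_fraction > 0 && s$n_breeds >= 2) {
      adm <- which(runif(n_tot) < s$admix_fraction)
      for (i in adm) {
        b <- match(labels[i], s$breed_names)
        partner <- sample(setdiff(seq_len(s$n_breeds), b), 1L)
        src1 <- ifelse(runif(L) < s$admix_m, b, partner)
        src2 <- ifelse(runif(L) < s$admix_m, b, partner)
        calls[i, ] <- rbinom(L, 1L, freqs[cbind(src1, seq_len(L))]) +
          rbinom(L, 1L, freqs[cbind(src2, seq_len(L))])
      }
    }
    loci <- data.frame(
      locus_id = colnames(freqs),
      chromosome = as.character(((seq_len(L) - 1L) %% 18L) + 1L),
      position_bp = as.integer(((seq_len(L) - 1L) %/% 18L + 1L) * 40000L),
      ref_allele = "A", alt_allele = "G", stringsAsFactors = FALSE)
    if (s$n_ld_pairs > 0) {
      if (2L * s$n_ld_pairs > L) stop_val("too many LD pairs for n_loci")
      for (k in seq_len(s$n_ld_pairs)) {
        src <- 2L * k - 1L; tgt <- 2L * k
        g <- calls[, src]
        # resample each allele copy from the individual's breed frequency
        # with probability ld_copy_error; otherwise copy it verbatim
        p_i <- freqs[cbind(match(labels, s$breed_names), tgt * 0 + src)]
        flip1 <- runif(n_tot) < s$ld_copy_error
        flip2 <- runif(n_tot) < s$ld_copy_error
        a1 <- ifelse(flip1, rbinom(n_tot, 1L, p_i), as.integer(g >= 1L))
        a2 <- ifelse(flip2, rbinom(n_tot, 1L, p_i), as.integer(g == 2L))
        calls[, tgt] <- a1 + a2
        loci$chromosome[tgt] <- loci$chromosome[src]
        loci$position_bp[tgt] <- loci$position_bp[src] + 1000L
      }
    }
    if (s$missing_rate > 0)
      calls[runif(n_tot * L) < s$missing_rate] <- NA_integer_
    ids <- paste0(labels, "_", stats::ave(seq_len(n_tot), labels,
                                          FUN = seq_along))
    dimnames(calls) <- list(ids, colnames(freqs))
    genotype_dataset(calls, labels, loci)
  })
}

#' Frozen benchmark scenarios
#'
#' `two_pop_simple`: 2 breeds, 30 samples each, 200 loci, moderate
#' divergence.  `british_pigs_like`: 14 breeds with the reference study's
#' sample sizes (21-73), 5000 loci, divergence tuned during development so
#' realized mean pairwise theta falls in 0.4-0.6, one weakly diverged close
#' pair (realized theta ~ 0.1), one strong outgroup (mean theta ~ 0.7), 2%
#' missing calls.  `close_pair_only`: just a weakly diverged pair.
#'
#' @param name one of `"two_pop_simple"`, `"british_pigs_like"`,
#'   `"close_pair_only"`.
#' @param seed optional master-seed override (the frozen scenarios carry
#'   fixed seeds).
#' @return a [sim_scenario()].
#' @export
make_benchmark_scenario <- function(name = c("two_pop_simple",
                                             "british_pigs_like",
                                             "close_pair_only"),
                                    seed = NULL) {
  name <- match.arg(name)
  sc <- switch(name,
    two_pop_simple = sim_scenario(
      n_breeds = 2, samples_per_breed = 30, n_loci = 200,
      breed_F = 0.3, seed = 101L),
    british_pigs_like = sim_scenario(
      n_breeds = 14,
      samples_per_breed = c(73, 30, 31, 24, 30, 30, 30, 34, 26, 24, 30, 21,
                            30, 33),
      n_loci = 5000,
      breed_F = c(0.45, 0.35, 0.50, 0.60, 0.60, 0.40, 0.45, 0.40, 0.52,
                  0.90, 0.55, 0.55, 0.58, 0.40),
      close_pairs = list(list(members = c(6L, 14L), F_pair = 0.10,
                              F_shared = 0.40)),
      missing_rate = 0.02, seed = 202L),
    close_pair_only = sim_scenario(
      n_breeds = 2, samples_per_breed = 30, n_loci = 500,
      breed_F = 0.3,
      close_pairs = list(list(members = c(1L, 2L), F_pair = 0.055,
                              F_shared = 0.3)),
      seed = 303L))
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  sc
}

#' One-call convenience: scenario -> genotype dataset
#'
#' @param scenario a [sim_scenario()].
#' @return a [genotype_dataset()].
#' @export
simulate_dataset <- function(scenario) {
  simulate_genotypes(simulate_breed_frequencies(scenario), scenario)
}
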