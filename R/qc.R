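#' QC configuration for call-rate filtering
#'
#' Defaults follow the reference-panel screening convention: loci must reach
#' an 80% call rate, evaluated within every breed (`per_breed`), so that
#' breed-specific missingness cannot masquerade as allele-frequency
#' divergence; samples must reach an 85% call rate.
#'
#' @param min_locus_call_rate fraction in \[0, 1\]; default 0.80.
#' @param call_rate_scope `"per_breed"` (a locus passes only if its call rate
#'   passes in every breed) or `"overall"`.
#' @param min_sample_call_rate fraction in \[0, 1\]; default 0.85.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_locus_call_rate = 0.80,
                      call_rate_scope = c("per_breed", "overall"),
                      min_sample_call_rate = 0.85) {
  assert_fraction(min_locus_call_rate, "min_locus_call_rate")
  assert_fraction(min_sample_call_rate, "min_sample_call_rate")
  structure(list(min_locus_call_rate = min_locus_call_rate,
                 call_rate_scope = match.arg(call_rate_scope),
                 min_sample_call_rate = min_sample_call_rate),
            class = "qc_config")
}

#' Filter loci and samples by call rate
#'
#' Loci are screened first (against the full sample set), then samples
#' against the retained loci, and the two steps repeat until stable, so the
#' returned dataset satisfies both thresholds simultaneously and the filter
#' is idempotent.  Under `per_breed` scope the governing locus statistic is
#' the minimum over breeds of the within-breed call rate.  Reported rates
#' are the ones that triggered each drop (first pass for survivors).
#'
#' @param data a [genotype_dataset()].
#' @param qc a [qc_config()].
#' @return a `qc_result`: list with the filtered `data`, a `locus_report`
#'   (`locus_id`, `call_rate`, `dropped`) and a `sample_report`
#'   (`sample_id`, `breed`, `call_rate`, `dropped`).
#' @export
filter_call_rate <- function(data, qc = qc_config()) {
  stopifnot(inherits(data, "genotype_dataset"), inherits(qc, "qc_config"))
  if (n_samples(data) == 0L || n_loci(data) == 0L)
    stop_val("dataset is empty")
  locus_rate_of <- function(obs, breed) {
    if (qc$call_rate_scope == "per_breed") {
      f <- factor(breed, levels = sort(unique(breed)))
      per_breed <- rowsum(obs + 0, f) / as.vector(table(f))
      apply(per_breed, 2L, min)
    } else colMeans(obs)
  }
  observed <- !is.na(data$calls)
  keep_loci <- rep(TRUE, ncol(observed))
  keep_samples <- rep(TRUE, nrow(observed))
  locus_rate <- rep(NA_real_, ncol(observed))
  sample_rate <- rep(NA_real_, nrow(observed))
  repeat {
    obs <- observed[keep_samples, keep_loci, drop = FALSE]
    lr <- locus_rate_of(obs, data$breed[keep_samples])
    locus_rate[keep_loci] <- lr
    drop_l <- lr < qc$min_locus_call_rate
    keep_loci[keep_loci] <- !drop_l
    if (!any(keep_loci))
      stop_val("call-rate filter removed every locus (empty panel)")
    sr <- rowMeans(observed[keep_samples, keep_loci, drop = FALSE])
    sample_rate[keep_samples] <- sr
    drop_s <- sr < qc$min_sample_call_rate
    keep_samples[keep_samples] <- !drop_s
    if (!any(keep_samples))
      stop_val("call-rate filter removed every sample")
    if (!any(drop_l) && !any(drop_s)) break
  }
  idx <- which(keep_loci)
  filtered <- genotype_dataset(
    data$calls[keep_samples, keep_loci, drop = FALSE],
    data$breed[keep_samples],
    data$loci[idx, , drop = FALSE])
  structure(list(
    data = filtered,
    locus_report = data.frame(locus_id = colnames(data$calls),
                              call_rate = unname(locus_rate),
                              dropped = !keep_loci, row.names = NULL,
                              stringsAsFactors = FALSE),
    sample_report = data.frame(sample_id = rownames(data$calls),
                               breed = unname(data$breed),
                               call_rate = unname(sample_rate),
                               dropped = !keep_samples, row.names = NULL,
                               stringsAsFactors = FALSE),
    config = qc), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("qc_result:", sum(x$locus_report$dropped), "loci and",
      sum(x$sample_report$dropped), "samples dropped;",
      n_loci(x$data), "loci x", n_samples(x$data), "samples retained\n")
  invisible(x)
}
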