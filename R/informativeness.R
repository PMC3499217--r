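#' Delta informativeness of a single locus
#'
#' Delta between two populations at a biallelic locus is the absolute
#' difference of their alternate-allele frequencies; the locus score is the
#' mean over all unordered breed pairs where both frequencies are defined.
#' Pairs with an undefined frequency (no observed alleles) are excluded from
#' the mean rather than scored zero -- absence of data is not evidence of
#' similarity -- and the number of usable pairs is reported.
#'
#' @param freqs numeric vector of per-breed alternate-allele frequencies at
#'   one locus (`NA` = undefined).
#' @return list with `pair_deltas` (named by breed pair when `freqs` is
#'   named), `delta_mean` (`NA` if fewer than two defined breeds) and
#'   `pairs_used`.
#' @export
delta_locus <- function(freqs) {
  ok <- which(!is.na(freqs))
  if (length(ok) < 2L)
    return(list(pair_deltas = numeric(0), delta_mean = NA_real_,
                pairs_used = 0L))
  pr <- utils::combn(ok, 2L)
  d <- abs(freqs[pr[1L, ]] - freqs[pr[2L, ]])
  if (!is.null(names(freqs)))
    names(d) <- paste(names(freqs)[pr[1L, ]], names(freqs)[pr[2L, ]],
                      sep = ":")
  list(pair_deltas = d, delta_mean = mean(d), pairs_used = ncol(pr))
}

#' Rank loci by mean pairwise delta
#'
#' Deterministic ranking by descending mean delta; ties are broken by
#' ascending locus id; loci with an undefined score sort last.
#'
#' @param data a QC-filtered [genotype_dataset()].
#' @return a `delta_ranking`: `data.frame` with `locus_id`, `delta_mean`,
#'   `pairs_used`, `rank`, sorted by rank.
#' @export
rank_markers <- function(data) {
  bc <- breed_counts(data)
  fr <- bc$freq
  B <- nrow(fr)
  if (B < 2L) stop_val("ranking needs at least two breeds")
  pairs <- utils::combn(B, 2L)
  sum_d <- numeric(ncol(fr))
  n_d <- integer(ncol(fr))
  for (k in seq_len(ncol(pairs))) {
    d <- abs(fr[pairs[1L, k], ] - fr[pairs[2L, k], ])
    ok <- !is.na(d)
    sum_d[ok] <- sum_d[ok] + d[ok]
    n_d[ok] <- n_d[ok] + 1L
  }
  delta_mean <- ifelse(n_d > 0L, sum_d / n_d, NA_real_)
  id <- colnames(fr)
  ord <- order(-replace(delta_mean, is.na(delta_mean), -Inf), id)
  out <- data.frame(locus_id = id[ord], delta_mean = delta_mean[ord],
                    pairs_used = n_d[ord], rank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("delta_ranking", "data.frame"))
}

#' Select the top-ranked marker panel
#'
#' @param ranking a [rank_markers()] result.
#' @param size integer between 1 and the number of ranked loci.
#' @return a `panel_selection`: character vector of locus ids in rank order,
#'   with a `size` attribute.
#' @export
select_panel <- function(ranking, size) {
  stopifnot(inherits(ranking, "delta_ranking"))
  if (!is.numeric(size) || length(size) != 1L || size < 1 ||
      size > nrow(ranking))
    stop_val("panel size must lie in [1, ", nrow(ranking), "]")
  structure(ranking$locus_id[seq_len(size)], size = as.integer(size),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("panel_selection:", attr(x, "size"), "loci (top-ranked first)\n")
  invisible(x)
}

resolve_panel <- function(data, panel) {
  if (is.null(panel)) return(colnames(data$calls))
  ids <- as.character(panel)
  miss <- setdiff(ids, colnames(data$calls))
  if (length(miss)) stop_val("panel locus not in dataset: ", miss[1L])
  ids
}

#' Self-assignment accuracy against cumulative panel size
#'
#' For each requested size `s`, runs leave-one-out self-assignment
#' ([self_assign_all()]) on the top-`s` ranked loci and records the
#' percentage of individuals assigned to their true breed -- the curve used
#' to choose how many markers a multiplex assay needs.
#'
#' @param data a [genotype_dataset()].
#' @param ranking a [rank_markers()] result on `data`.
#' @param sizes strictly increasing positive integers, each at most the
#'   number of ranked loci.
#' @return an `assignment_curve`: `data.frame` with `panel_size` and
#'   `pct_correct`, plus attribute `n_individuals`.
#' @export
assignment_curve <- function(data, ranking, sizes) {
  stopifnot(inherits(ranking, "delta_ranking"))
  if (length(sizes) == 0L || any(sizes < 1) || is.unsorted(sizes, strictly = TRUE))
    stop_val("sizes must be strictly increasing positive integers")
  if (max(sizes) > nrow(ranking))
    stop_val("largest size exceeds the number of ranked loci")
  pct <- vapply(sizes, function(s) {
    rec <- self_assign_all(data, select_panel(ranking, s))
    100 * mean(rec$assigned_breed == rec$true_breed)
  }, numeric(1))
  structure(data.frame(panel_size = as.integer(sizes), pct_correct = pct),
            n_individuals = n_samples(data),
            class = c("assignment_curve", "data.frame"))
}

#' @export
plot.assignment_curve <- function(x, ...) {
  graphics::plot(x$panel_size, x$pct_correct, type = "b", pch = 16,
                 xlab = "number of top-ranked SNPs",
                 ylab = "% individuals correctly self-assigned",
                 ylim = c(min(x$pct_correct) - 1, 100), ...)
  invisible(x)
}

#' Screen a panel for within-breed linkage disequilibrium
#'
#' Computes EM-based r-squared ([r2_pair()]) for every same-chromosome pair
#' of mapped panel loci within every breed, and reports the pairs exceeding
#' the threshold in at least one breed.  Informative-marker selection tends
#' to co-opt clustered selected regions, so post-hoc LD screening flags
#' redundant panel members.
#'
#' @param data a [genotype_dataset()].
#' @param panel a [select_panel()] result (or character vector of locus ids);
#'   `NULL` = all loci.
#' @param r2_threshold report pairs with r-squared strictly above this value
#'   (default 0.4).
#' @return `data.frame` with `locus_a`, `locus_b`, `chromosome`, `breed`,
#'   `r_squared` (one row per breed in which the pair exceeds the threshold).
#' @export
panel_ld_screen <- function(data, panel = NULL, r2_threshold = 0.4) {
  ids <- resolve_panel(data, panel)
  map <- data$loci[match(ids, data$loci$locus_id), ]
  map <- map[map$chromosome != "Undetermined", , drop = FALSE]
  out <- list()
  for (chr in unique(map$chromosome)) {
    loc <- map$locus_id[map$chromosome == chr]
    if (length(loc) < 2L) next
    pr <- utils::combn(loc, 2L)
    for (k in seq_len(ncol(pr))) {
      for (b in breeds(data)) {
        r <- r2_pair(data, b, pr[1L, k], pr[2L, k])
        if (!is.na(r$r_squared) && r$r_squared > r2_threshold)
          out[[length(out) + 1L]] <- data.frame(
            locus_a = pr[1L, k], locus_b = pr[2L, k], chromosome = chr,
            breed = b, r_squared = r$r_squared,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      chromosome = character(0), breed = character(0),
                      r_squared = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
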