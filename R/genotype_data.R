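#' Diploid biallelic SNP genotype dataset with breed labels
#'
#' The central container of the package: an individuals x loci matrix of
#' alternate-allele dosages (0, 1, 2, or `NA` for a missing call), one breed
#' label per individual, and a locus map (chromosome, physical position,
#' ref/alt alleles).
#'
#' @param calls integer matrix, individuals in rows, loci in columns; entries
#'   must be 0, 1, 2 or `NA`.  Row names are sample identifiers, column names
#'   locus identifiers (generated if absent).
#' @param breed character vector of breed labels, one per row of `calls`.
#' @param loci optional `data.frame` with columns `locus_id`, `chromosome`,
#'   `position_bp`, `ref_allele`, `alt_allele`.  `chromosome` is an autosome
#'   number, `"X"`, or `"Undetermined"`; `position_bp` is 1-based and must be
#'   present exactly when the chromosome is determined.  When `NULL`, all loci
#'   are recorded as unmapped.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `calls`, `breed` (named by sample) and `loci`.
#' @export
genotype_dataset <- function(calls, breed, loci = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  breed <- as.character(breed)
  if (length(breed) != nrow(calls))
    stop_val("breed must have one label per sample")
  names(breed) <- rownames(calls)
  if (is.null(loci)) {
    loci <- data.frame(locus_id = colnames(calls),
                       chromosome = "Undetermined",
                       position_bp = NA_integer_,
                       ref_allele = "A", alt_allele = "G",
                       stringsAsFactors = FALSE)
  }
  obj <- structure(list(calls = calls, breed = breed, loci = loci),
                   class = "genotype_dataset")
  validate_genotype_dataset(obj)
}

validate_genotype_dataset <- function(x) {
  calls <- x$calls
  if (anyDuplicated(rownames(calls)))
    stop_val("duplicate sample id: ",
             rownames(calls)[duplicated(rownames(calls))][1L])
  if (anyDuplicated(colnames(calls)))
    stop_val("duplicate locus id: ",
             colnames(calls)[duplicated(colnames(calls))][1L])
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad))
    stop_val("genotype calls must be 0, 1, 2 or NA")
  if (any(is.na(x$breed)) || any(!nzchar(x$breed)))
    stop_val("every sample needs a non-empty breed label")
  loci <- x$loci
  need <- c("locus_id", "chromosome", "position_bp", "ref_allele", "alt_allele")
  if (!all(need %in% names(loci)))
    stop_val("loci table must have columns: ", paste(need, collapse = ", "))
  if (nrow(loci) != ncol(calls) || !identical(loci$locus_id, colnames(calls)))
    stop_val("loci table must match call-matrix columns (same ids, same order)")
  unmapped <- loci$chromosome == "Undetermined"
  if (any(!unmapped & is.na(loci$position_bp)))
    stop_val("mapped loci must carry a position")
  if (any(unmapped & !is.na(loci$position_bp)))
    stop_val("unmapped loci must not carry a position")
  if (any(!is.na(loci$position_bp) & loci$position_bp < 1))
    stop_val("positions are 1-based and must be >= 1")
  x
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$calls), "samples x", ncol(x$calls),
      "loci;", length(unique(x$breed)), "breeds\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_dataset
#' @param x a `genotype_dataset`.
#' @export
n_samples <- function(x) nrow(x$calls)

#' @rdname genotype_dataset
#' @export
n_loci <- function(x) ncol(x$calls)

#' @rdname genotype_dataset
#' @export
breeds <- function(x) sort(unique(unname(x$breed)))

#' Restrict a dataset to a subset of loci or samples
#'
#' @param data a `genotype_dataset`.
#' @param locus_ids,sample_ids identifiers to keep, in the requested order.
#' @return a new `genotype_dataset`.
#' @export
subset_loci <- function(data, locus_ids) {
  miss <- setdiff(locus_ids, colnames(data$calls))
  if (length(miss)) stop_val("unknown locus id: ", miss[1L])
  idx <- match(locus_ids, data$loci$locus_id)
  genotype_dataset(data$calls[, locus_ids, drop = FALSE], data$breed,
                   data$loci[idx, , drop = FALSE])
}

#' @rdname subset_loci
#' @export
subset_samples <- function(data, sample_ids) {
  miss <- setdiff(sample_ids, rownames(data$calls))
  if (length(miss)) stop_val("unknown sample id: ", miss[1L])
  genotype_dataset(data$calls[sample_ids, , drop = FALSE],
                   data$breed[sample_ids], data$loci)
}

#' Per-breed allele counts and frequencies
#'
#' Counts alternate alleles among the observed (non-missing) calls of one
#' breed's samples.  With `leave_out`, both allele copies of that sample are
#' removed at its observed loci before counting -- the "leave-one-out"
#' re-estimation used throughout self-assignment.
#'
#' @param data a `genotype_dataset`.
#' @param breed breed label present in `data`.
#' @param leave_out optional sample id belonging to `breed`.
#' @return an `allele_freq_table`: a `data.frame` with columns `locus_id`,
#'   `n_alt`, `n_obs` and `freq_alt` (`NA` where no alleles were observed),
#'   with the breed and any left-out sample stored as attributes.
#' @export
estimate_frequencies <- function(data, breed, leave_out = NULL) {
  if (!breed %in% data$breed) stop_val("unknown breed: ", breed)
  rows <- data$calls[data$breed == breed, , drop = FALSE]
  n_alt <- colSums(rows, na.rm = TRUE)
  n_obs <- 2L * colSums(!is.na(rows))
  if (!is.null(leave_out)) {
    if (!leave_out %in% rownames(rows))
      stop_val("sample ", leave_out, " is not in breed ", breed)
    g <- rows[leave_out, ]
    obs <- !is.na(g)
    n_alt[obs] <- n_alt[obs] - g[obs]
    n_obs[obs] <- n_obs[obs] - 2L
  }
  freq <- ifelse(n_obs > 0, n_alt / n_obs, NA_real_)
  structure(data.frame(locus_id = colnames(data$calls),
                       n_alt = as.integer(n_alt), n_obs = as.integer(n_obs),
                       freq_alt = freq, row.names = NULL,
                       stringsAsFactors = FALSE),
            breed = breed, leave_out = leave_out,
            class = c("allele_freq_table", "data.frame"))
}

# Counts for all breeds at once: matrices breeds x loci.
breed_counts <- function(data, locus_ids = NULL) {
  calls <- data$calls
  if (!is.null(locus_ids)) calls <- calls[, locus_ids, drop = FALSE]
  f <- factor(data$breed, levels = breeds(data))
  alt <- calls
  alt[is.na(alt)] <- 0L
  n_alt <- rowsum(alt, f)
  n_obs <- 2L * rowsum((!is.na(calls)) + 0L, f)
  list(breeds = levels(f), n_alt = n_alt, n_obs = n_obs,
       freq = ifelse(n_obs > 0, n_alt / n_obs, NA_real_))
}
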