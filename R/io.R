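#' Read breed-labelled SNP genotypes from PED/MAP or CSV
#'
#' Two dialects are supported.  `ped_map`: PLINK-style text, the standard
#' 6-column PED prefix (family id is taken as the breed label) followed by two
#' allele symbols per locus ("0 0" = missing), with a 4-column MAP file
#' (chromosome, locus id, genetic distance, bp position; chromosome 0 /
#' position 0 mean unmapped).  `csv`: one header row, samples as rows, columns
#' `sample_id`, `breed`, then one column per locus holding the alt-allele
#' dosage (0/1/2, empty = missing); the locus map travels in a sibling file
#' `<stem>.loci.csv` and the pair round-trips bit-exactly through
#' [write_genotypes()].
#'
#' @param path for `ped_map`, the path to the `.ped` file or the common
#'   prefix of the `.ped`/`.map` pair; for `csv`, the genotype CSV path.
#' @param format `"ped_map"` or `"csv"`.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("ped_map", "csv")) {
  format <- match.arg(format)
  if (format == "ped_map") read_ped_map(path) else read_genotype_csv(path)
}

#' Write a genotype dataset
#'
#' Inverse of [read_genotypes()]; see there for the dialects.  For PED output,
#' dosages are expanded to allele pairs using the locus map's ref/alt symbols.
#'
#' @param data a [genotype_dataset()].
#' @inheritParams read_genotypes
#' @return the paths written, invisibly.
#' @export
write_genotypes <- function(data, path, format = c("ped_map", "csv")) {
  format <- match.arg(format)
  if (format == "ped_map") write_ped_map(data, path) else
    write_genotype_csv(data, path)
}

ped_paths <- function(path) {
  stem <- sub("\\.ped$", "", path)
  list(ped = paste0(stem, ".ped"), map = paste0(stem, ".map"))
}

csv_paths <- function(path) {
  stem <- sub("\\.csv$", "", path)
  list(geno = paste0(stem, ".csv"), loci = paste0(stem, ".loci.csv"))
}

read_ped_map <- function(path) {
  p <- ped_paths(path)
  for (f in unlist(p)) if (!file.exists(f)) stop_val("file not found: ", f)
  map <- read.table(p$map, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chromosome", "locus_id", "cm", "position_bp"),
                    colClasses = c("character", "character", "character",
                                   "integer"))
  if (anyDuplicated(map$locus_id))
    stop_val("duplicate locus id in MAP: ",
             map$locus_id[duplicated(map$locus_id)][1L])
  unmapped <- map$chromosome %in% c("0", "Undetermined") | map$position_bp == 0
  chromosome <- ifelse(unmapped, "Undetermined", map$chromosome)
  position <- ifelse(unmapped, NA_integer_, map$position_bp)
  L <- nrow(map)

  lines <- readLines(p$ped)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop_val("empty PED file: ", p$ped)
  a1 <- matrix("", n, L); a2 <- matrix("", n, L)
  fid <- character(n); iid <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(tok) != 6L + 2L * L)
      stop_val("PED parse error at line ", i, ": expected ", 6L + 2L * L,
               " fields, found ", length(tok))
    fid[i] <- tok[1L]; iid[i] <- tok[2L]
    g <- tok[-(1:6)]
    a1[i, ] <- g[c(TRUE, FALSE)]
    a2[i, ] <- g[c(FALSE, TRUE)]
  }
  if (anyDuplicated(iid))
    stop_val("duplicate sample id in PED: ", iid[duplicated(iid)][1L])
  half_missing <- xor(a1 == "0", a2 == "0")
  if (any(half_missing))
    stop_val("half-missing genotype (one allele coded 0) at line ",
             which(rowSums(half_missing) > 0)[1L])
  calls <- matrix(NA_integer_, n, L, dimnames = list(iid, map$locus_id))
  ref <- character(L); alt <- character(L)
  for (j in seq_len(L)) {
    obs <- a1[, j] != "0"
    alleles <- sort(unique(c(a1[obs, j], a2[obs, j])))
    if (length(alleles) > 2L)
      stop_val("more than two alleles at locus ", map$locus_id[j], ": ",
               paste(alleles, collapse = "/"))
    ref[j] <- if (length(alleles) >= 1L) alleles[1L] else "A"
    alt[j] <- if (length(alleles) == 2L) alleles[2L] else NA_character_
    dose <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    dose[!obs] <- NA_integer_
    if (is.na(alt[j])) dose[obs] <- 0L  # monomorphic
    calls[, j] <- as.integer(dose)
  }
  loci <- data.frame(locus_id = map$locus_id, chromosome = chromosome,
                     position_bp = as.integer(position),
                     ref_allele = ref, alt_allele = alt,
                     stringsAsFactors = FALSE)
  genotype_dataset(calls, fid, loci)
}

write_ped_map <- function(data, path) {
  p <- ped_paths(path)
  loci <- data$loci
  chrom <- ifelse(loci$chromosome == "Undetermined", "0", loci$chromosome)
  pos <- ifelse(is.na(loci$position_bp), 0L, loci$position_bp)
  writeLines(paste(chrom, loci$locus_id, 0, pos, sep = "\t"), p$map)
  ref <- loci$ref_allele
  alt <- ifelse(is.na(loci$alt_allele), loci$ref_allele, loci$alt_allele)
  n <- nrow(data$calls); L <- ncol(data$calls)
  out <- character(n)
  for (i in seq_len(n)) {
    g <- data$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    out[i] <- paste(c(data$breed[i], rownames(data$calls)[i], "0", "0", "0",
                      "-9", rbind(a1, a2)), collapse = "\t")
  }
  writeLines(out, p$ped)
  invisible(unlist(p))
}

read_genotype_csv <- function(path) {
  p <- csv_paths(path)
  if (!file.exists(p$geno)) stop_val("file not found: ", p$geno)
  geno <- utils::read.csv(p$geno, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(names(geno)[1:2], c("sample_id", "breed")))
    stop_val("genotype CSV must start with columns sample_id, breed")
  if (anyDuplicated(geno$sample_id))
    stop_val("duplicate sample id in CSV: ",
             geno$sample_id[duplicated(geno$sample_id)][1L])
  calls <- as.matrix(geno[, -(1:2), drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- geno$sample_id
  loci <- NULL
  if (file.exists(p$loci)) {
    loci <- utils::read.csv(p$loci, stringsAsFactors = FALSE,
                            colClasses = c(locus_id = "character",
                                           chromosome = "character",
                                           position_bp = "integer",
                                           ref_allele = "character",
                                           alt_allele = "character"))
    loci$alt_allele[!is.na(loci$alt_allele) & loci$alt_allele == ""] <-
      NA_character_
  }
  genotype_dataset(calls, geno$breed, loci)
}

write_genotype_csv <- function(data, path) {
  p <- csv_paths(path)
  df <- data.frame(sample_id = rownames(data$calls),
                   breed = unname(data$breed),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$calls, check.names = FALSE))
  utils::write.csv(df, p$geno, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(data$loci, p$loci, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(unlist(p))
}
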