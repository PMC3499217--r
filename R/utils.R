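# Internal helpers shared across modules.

# Deterministic child seeds derived from one master seed.  Keeps every
# stage's RNG stream independent while staying below 2^31 (R integer range).
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  offsets <- c(frequencies = 11L, genotypes = 23L, exclusion = 37L,
               bootstrap = 53L, queries = 71L, pipeline = 89L, admix = 97L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((abs(master) %% 2097152) * 1009 + offsets[[stage]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_val <- function(...) stop(..., call. = FALSE)

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_val(name, " must be a single number in [", lo, ", ", hi, "]")
  invisible(x)
}
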