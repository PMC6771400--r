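# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulations never perturb user RNG flow.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index; keeps independent
# sampling streams reproducible while staying inside 32-bit integer range.
child_seed <- function(seed, stream) {
  # double arithmetic: exact far beyond 32-bit range, result folded back in
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %% 2147483647)
}

# x * log(y) with the 0 * log(0) == 0 convention used in binomial likelihoods.
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

# Junction key: genomic-left ("donor" column) / genomic-right coordinates of
# the intron in 0-based half-open convention, plus chrom and strand.
junction_key <- function(chrom, donor, acceptor, strand) {
  if (length(chrom) == 0) return(character(0))
  paste0(chrom, ":", donor, "-", acceptor, ":", strand)
}

# Exon-intron boundary key; side is the biological end of the intron (5p/3p).
boundary_key <- function(chrom, pos, side, strand) {
  if (length(chrom) == 0) return(character(0))
  paste0(chrom, ":", pos, ":", side, ":", strand)
}

split_keys <- function(keys) strsplit(keys, ";", fixed = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
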