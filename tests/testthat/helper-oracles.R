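# Independent oracles used across the suite. These reimplement small pieces
# of arithmetic from first principles (brute force or closed form) so that
# package results can be checked against a second, independent route.

# Bayes factor via dbinom likelihoods (binomial coefficients cancel in the
# BIC difference because k and n are identical under both hypotheses).
oracle_bf <- function(k1, n1, k2, n2) {
  N <- n1 + n2
  p0 <- (k1 + k2) / N
  ll0 <- stats::dbinom(k1, n1, p0, log = TRUE) + stats::dbinom(k2, n2, p0, log = TRUE)
  ll1 <- stats::dbinom(k1, n1, k1 / n1, log = TRUE) +
    stats::dbinom(k2, n2, k2 / n2, log = TRUE)
  exp(((-2 * ll0 + log(N)) - (-2 * ll1 + 2 * log(N))) / 2)
}

# Brute-force per-read junction/boundary inspection of SAM text lines.
oracle_count_sam <- function(lines, boundaries, min_overhang = 6L) {
  lines <- lines[!startsWith(lines, "@")]
  jkeys <- character(0); bkeys <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) next
    flag <- as.integer(f[2]); mapq <- as.integer(f[5])
    if (bitwAnd(flag, 0x900) != 0 || mapq == 0) next
    strand <- if (bitwAnd(flag, 16L) > 0) "-" else "+"
    ops <- regmatches(f[6], gregexpr("[0-9]+[A-Z=]", f[6]))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    type <- sub("[0-9]+", "", ops)
    pos0 <- as.integer(f[4]) - 1L
    blocks <- list(); cur_start <- pos0; cur_len <- 0L
    for (i in seq_along(ops)) {
      if (type[i] %in% c("M", "=", "X")) {
        cur_len <- cur_len + lens[i]
      } else if (type[i] %in% c("N", "D")) {
        blocks[[length(blocks) + 1L]] <- c(cur_start, cur_start + cur_len)
        cur_start <- cur_start + cur_len + lens[i]
        cur_len <- 0L
      }
    }
    blocks[[length(blocks) + 1L]] <- c(cur_start, cur_start + cur_len)
    if (length(blocks) > 1) {
      for (i in seq_len(length(blocks) - 1L)) {
        b1 <- blocks[[i]]; b2 <- blocks[[i + 1L]]
        if ((b1[2] - b1[1]) >= min_overhang && (b2[2] - b2[1]) >= min_overhang) {
          jkeys <- c(jkeys, paste0(f[3], ":", b1[2], "-", b2[1], ":", strand))
        }
      }
    }
    for (j in seq_len(nrow(boundaries))) {
      b <- boundaries[j, ]
      if (b$chrom != f[3] || b$strand != strand) next
      span <- any(vapply(blocks, function(bl) {
        bl[1] <= b$boundary_pos - min_overhang && bl[2] >= b$boundary_pos + min_overhang
      }, logical(1)))
      if (span) {
        bkeys <- c(bkeys, paste0(b$chrom, ":", b$boundary_pos, ":", b$side, ":", b$strand))
      }
    }
  }
  list(junctions = table(jkeys), boundaries = table(bkeys))
}

# Brute-force Ward.D2 agglomeration (Lance-Williams recurrence) on a small
# Euclidean distance matrix; returns merge heights in order.
oracle_ward_heights <- function(mat) {
  d2 <- as.matrix(stats::dist(mat))^2
  n <- nrow(d2)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  D <- d2
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in active) for (j in active) {
      if (i < j && D[i, j] < bestv) { bestv <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      D[i, k] <- D[k, i] <- ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] -
                               nk * bestv) / (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Classical MDS by direct double centering of the squared distance matrix.
oracle_cmds <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  e$vectors[, seq_len(k)] %*% diag(sqrt(pmax(e$values[seq_len(k)], 0)))
}

# Exact two-sample one-sided Wilcoxon / rank-based p by full enumeration of
# group assignments.
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); m <- length(a)
  w_obs <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(n, m)
  w_all <- apply(combos, 2, function(i) sum(rank(pooled)[i]) - m * (m + 1) / 2)
  ew <- m * (length(b)) / 2
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

# Exact one-sided two-sample KS p (D+ of F_b - F_a on a grid) by enumeration.
oracle_ks_dplus_p <- function(a, b, grid) {
  dplus <- function(x, y) max(stats::ecdf(y)(grid) - stats::ecdf(x)(grid))
  obs <- dplus(a, b)
  pooled <- c(a, b)
  combos <- utils::combn(length(pooled), length(a))
  stat <- apply(combos, 2, function(i) dplus(pooled[i], pooled[-i]))
  mean(stat >= obs - 1e-12)
}

# Tiny two-transcript exon table shared by several catalog tests.
toy_exons <- function(kind = c("SE", "RI"), strand = "+") {
  kind <- match.arg(kind)
  if (kind == "SE") {
    data.frame(
      gene_id = "g1",
      transcript_id = rep(c("t1", "t2"), c(3, 2)),
      chrom = "chr1", strand = strand,
      start = c(100, 300, 500, 100, 500),
      end = c(200, 400, 600, 200, 600))
  } else {
    data.frame(
      gene_id = "g1",
      transcript_id = rep(c("t1", "t2"), c(2, 1)),
      chrom = "chr1", strand = strand,
      start = c(100, 300, 100),
      end = c(200, 400, 400))
  }
}

# Thin conveniences for tests.
catalog_boundaries_for_test <- function(events) snsplice:::catalog_boundaries(events)
empty_counts <- function() {
  data.frame(chrom = character(), donor = integer(), acceptor = integer(),
             strand = character(), count = integer())
}
with_seed_for_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
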