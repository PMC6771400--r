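#' Bayes factor for a difference in binomial proportions (BIC approximation)
#'
#' Compares H1 (two independent binomial proportions, MLEs k1/n1 and k2/n2)
#' against H0 (one shared proportion, MLE (k1+k2)/(n1+n2)) through the BIC
#' approximation to the Bayes factor:
#' `BIC_m = -2 log Lhat_m + p_m log(n1+n2)` with p0 = 1, p1 = 2 free
#' parameters, and `BF10 = exp((BIC0 - BIC1) / 2)`. Binomial coefficients
#' cancel between models; `0 * log(0)` is taken as 0. When the two observed
#' proportions coincide the likelihoods are equal and
#' `BF10 = (n1 + n2)^(-1/2)` exactly.
#'
#' All arguments are vectorized.
#'
#' @param k1,n1,k2,n2 inclusion counts and totals in the two samples.
#' @return BF10 (>= 0); NA where either total is 0.
#' @export
bayes_factor_binomial <- function(k1, n1, k2, n2) {
  stopifnot(all(k1 >= 0 & k1 <= n1, na.rm = TRUE),
            all(k2 >= 0 & k2 <= n2, na.rm = TRUE))
  N <- n1 + n2
  p0 <- (k1 + k2) / N
  p1a <- k1 / n1
  p1b <- k2 / n2
  ll0 <- xlogy(k1 + k2, p0) + xlogy(N - k1 - k2, 1 - p0)
  ll1 <- xlogy(k1, p1a) + xlogy(n1 - k1, 1 - p1a) +
    xlogy(k2, p1b) + xlogy(n2 - k2, 1 - p1b)
  bic0 <- -2 * ll0 + 1 * log(N)
  bic1 <- -2 * ll1 + 2 * log(N)
  bf <- exp((bic0 - bic1) / 2)
  bf[n1 == 0 | n2 == 0] <- NA_real_
  bf
}

#' Call differential splicing between two samples
#'
#' An event is significant when all three criteria hold: at least `min_reads`
#' informative reads in both samples, an isoform-ratio change of at least
#' `min_delta`, and a Bayes factor of at least `min_bf`. Inclusion and
#' exclusion supports are rounded half-to-even to integers before the Bayes
#' factor (junction averaging can make them fractional). Events present in
#' only one table are emitted non-significant with a missing-data flag.
#'
#' @param psi_a,psi_b PSI tables from [estimate_psi()] (columns event_id, I,
#'   E, n, psi; a `kind` column is carried through when present).
#' @param min_reads minimum informative reads per sample.
#' @param min_delta minimum |delta psi|.
#' @param min_bf minimum Bayes factor.
#' @return data frame: event_id (kind), psi_a, psi_b, delta_psi, n_a, n_b,
#'   bayes_factor, significant, direction, missing_data.
#' @export
call_differential <- function(psi_a, psi_b, min_reads = 20, min_delta = 0.10,
                              min_bf = 1) {
  keep <- intersect(c("event_id", "kind", "I", "E", "n", "psi"), names(psi_a))
  m <- merge(psi_a[, keep], psi_b[, setdiff(keep, "kind")],
             by = "event_id", all = TRUE, suffixes = c("_a", "_b"))
  missing_data <- is.na(m$n_a) | is.na(m$n_b)
  k1 <- round(m$I_a); e1 <- round(m$E_a)
  k2 <- round(m$I_b); e2 <- round(m$E_b)
  bf <- rep(NA_real_, nrow(m))
  ok <- !missing_data & (k1 + e1) > 0 & (k2 + e2) > 0
  bf[ok] <- bayes_factor_binomial(k1[ok], k1[ok] + e1[ok], k2[ok], k2[ok] + e2[ok])
  delta <- m$psi_b - m$psi_a
  sig <- !missing_data & m$n_a >= min_reads & m$n_b >= min_reads &
    !is.na(delta) & abs(delta) >= min_delta & !is.na(bf) & bf >= min_bf
  out <- data.frame(event_id = m$event_id,
                    psi_a = m$psi_a, psi_b = m$psi_b, delta_psi = delta,
                    n_a = m$n_a, n_b = m$n_b, bayes_factor = bf,
                    significant = sig,
                    direction = ifelse(!sig, "none",
                                       ifelse(delta > 0, "increased_inclusion",
                                              "increased_exclusion")),
                    missing_data = missing_data)
  if ("kind" %in% names(m)) out <- cbind(out[1], kind = m$kind, out[-1])
  out
}

#' Per-gene intron counts and significantly retained introns
#'
#' Restricted to retained-intron events: counts, per gene, the annotated
#' introns and those called significantly more retained (delta psi > 0 and
#' significant). Also returns the (n_introns, n_retained) multiplicity table
#' used for the dot-size scatter display.
#'
#' @param calls output of [call_differential()] with a `kind` column.
#' @param genes gene table with gene_id and n_introns.
#' @param events event catalog mapping event_id to gene_id (only needed when
#'   `calls` lacks a gene_id column).
#' @return list with `per_gene` (gene_id, n_introns, n_retained) and
#'   `multiplicity` (n_introns, n_retained, n_genes).
#' @export
introns_per_gene_retention <- function(calls, genes, events = NULL) {
  ri <- calls[calls$kind == "RI" & !calls$missing_data, , drop = FALSE]
  if (!"gene_id" %in% names(ri)) {
    ri <- merge(ri, events[, c("event_id", "gene_id")], by = "event_id")
  }
  retained <- ri$significant & ri$delta_psi > 0
  cnt <- tapply(retained, ri$gene_id, sum)
  per_gene <- data.frame(gene_id = genes$gene_id,
                         n_introns = genes$n_introns,
                         n_retained = as.integer(cnt[genes$gene_id]))
  per_gene$n_retained[is.na(per_gene$n_retained)] <- 0L
  mult <- stats::aggregate(gene_id ~ n_introns + n_retained, per_gene, length)
  names(mult)[3] <- "n_genes"
  list(per_gene = per_gene, multiplicity = mult)
}

#' Overlap of significant event sets across conditions
#'
#' @param sets named list mapping condition to its significant event ids.
#' @return list with `pairs` (condition_a, condition_b, shared,
#'   fraction_of_a = |A intersect B| / |A|) and `membership` (events x
#'   conditions logical matrix).
#' @export
overlap_across_conditions <- function(sets) {
  if (length(sets) < 2) stopf("need >= 2 conditions")
  cond <- names(sets)
  grid <- expand.grid(condition_a = cond, condition_b = cond,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$condition_a != grid$condition_b, ]
  grid$shared <- mapply(function(a, b) length(intersect(sets[[a]], sets[[b]])),
                        grid$condition_a, grid$condition_b)
  sizes <- lengths(sets)
  grid$fraction_of_a <- ifelse(sizes[grid$condition_a] > 0,
                               grid$shared / sizes[grid$condition_a], NA_real_)
  if (any(sizes == 0)) warnf("empty significant set: overlap fraction undefined")
  all_ev <- sort(unique(unlist(sets)))
  membership <- matrix(vapply(sets, function(s) all_ev %in% s,
                              logical(length(all_ev))),
                       nrow = length(all_ev),
                       dimnames = list(all_ev, names(sets)))
  rownames(grid) <- NULL
  list(pairs = grid, membership = membership)
}

#' Monotonicity of a dose-response psi trajectory
#'
#' A trajectory is monotone when it is non-strictly increasing or decreasing
#' within tolerance `eps` (flat series count as monotone). Spearman's rho
#' against dose rank is reported alongside.
#'
#' @param psi inclusion levels at ascending doses (>= 3 defined values).
#' @param eps tolerance (psi units) on violations of monotonicity.
#' @return list with monotone, direction ("increasing", "decreasing",
#'   "flat" or "none"), rho.
#' @export
dose_response_trend <- function(psi, eps = 0.02) {
  psi <- psi[!is.na(psi)]
  if (length(psi) < 3) {
    warnf("fewer than 3 defined doses: trend undefined")
    return(list(monotone = NA, direction = NA_character_, rho = NA_real_))
  }
  d <- diff(psi)
  up <- all(d >= -eps); down <- all(d <= eps)
  rho <- suppressWarnings(stats::cor(seq_along(psi), psi, method = "spearman"))
  direction <- if (up && down) "flat" else if (up) "increasing"
    else if (down) "decreasing" else "none"
  list(monotone = up || down, direction = direction, rho = rho)
}

#' Classical MDS of samples on Canberra distances over variable events
#'
#' Events are first restricted to those alternatively spliced with more than
#' `min_reads` informative reads in at least one sample, then the `top_n`
#' events with the largest cross-sample psi variance are retained. Pairwise
#' Canberra distances (sum of |x_i - y_i| / |x_i + y_i|, terms with zero
#' denominator contributing 0) feed classical multidimensional scaling
#' (principal coordinates). Coordinates are centered; each axis's sign is
#' fixed so the first sample is non-negative.
#'
#' @param psi_matrix events x samples psi matrix.
#' @param n_matrix matching informative-read matrix.
#' @param top_n number of most-variable events to use.
#' @param min_reads read-support threshold for the event filter.
#' @return list with `coords` (samples x 2), `events_used`, `dist`.
#' @export
mds_canberra <- function(psi_matrix, n_matrix, top_n = 100L, min_reads = 20) {
  if (ncol(psi_matrix) < 3) stopf("MDS needs >= 3 samples")
  keep <- apply(n_matrix > min_reads, 1, any) &
    stats::complete.cases(psi_matrix)
  m <- psi_matrix[keep, , drop = FALSE]
  v <- apply(m, 1, stats::var)
  m <- m[order(v, decreasing = TRUE)[seq_len(min(top_n, nrow(m)))], , drop = FALSE]
  d <- canberra_dist(t(m))
  if (all(d == 0)) {          # identical samples: a single point
    xy <- matrix(0, ncol(m), 2, dimnames = list(colnames(m), NULL))
  } else {
    xy <- stats::cmdscale(d, k = 2)
    if (ncol(xy) < 2) {       # degenerate geometry collapses an axis
      xy <- cbind(xy, matrix(0, nrow(xy), 2 - ncol(xy)))
      rownames(xy) <- colnames(m)
    }
  }
  xy <- scale(xy, center = TRUE, scale = FALSE)
  for (j in 1:2) if (xy[1, j] < 0) xy[, j] <- -xy[, j]
  colnames(xy) <- c("MDS1", "MDS2")
  list(coords = xy, events_used = rownames(m), dist = d)
}

# Canberra distance matrix over rows; terms with |x_i + y_i| = 0 contribute 0
# (base dist() instead rescales such terms as missing).
canberra_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    num <- abs(m[i, ] - m[j, ])
    den <- abs(m[i, ] + m[j, ])
    term <- ifelse(den == 0, 0, num / den)
    d[i, j] <- d[j, i] <- sum(term)
  }
  stats::as.dist(d)
}
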