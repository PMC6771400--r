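#' Filter cohort events on read support and detection frequency
#'
#' Keeps events with at least `min_reads` informative reads in the reference
#' sample (the cell-line anchor) and in at least
#' `ceiling(min_detect_frac * n_patients)` patients — removing events whose
#' expression is confined to either the in vitro or the in vivo setting.
#'
#' @param n_matrix events x samples informative-read matrix; columns include
#'   the reference sample and the patient samples.
#' @param reference_sample column name of the reference.
#' @param patient_samples column names of the patients (default: all columns
#'   except the reference).
#' @param min_reads read-support threshold.
#' @param min_detect_frac minimum fraction of patients detecting the event.
#' @return character vector of surviving event ids (rownames).
#' @export
filter_cohort_events <- function(n_matrix, reference_sample,
                                 patient_samples = NULL,
                                 min_reads = 20, min_detect_frac = 0.20) {
  if (!reference_sample %in% colnames(n_matrix)) {
    stopf("reference sample '%s' absent", reference_sample)
  }
  patient_samples <- patient_samples %||%
    setdiff(colnames(n_matrix), reference_sample)
  need <- ceiling(min_detect_frac * length(patient_samples))
  det <- rowSums(n_matrix[, patient_samples, drop = FALSE] >= min_reads)
  keep <- n_matrix[, reference_sample] >= min_reads & det >= need
  rownames(n_matrix)[keep]
}

#' Pooled psi distributions per sensitivity stratum
#'
#' Pools defined psi values across samples within each event stratum (e.g.
#' KD-sensitive vs -insensitive, optionally split by inclusion/exclusion
#' direction) and summarizes heterogeneity as the intermediate-psi mass: the
#' fraction of values inside `band` — heterogeneous splicing across a cohort
#' shows up as mass between the fully-excluded and fully-included extremes.
#'
#' @param psi_matrix events x samples psi matrix.
#' @param labels named stratum label per event (names = event ids).
#' @param band inclusive intermediate-psi interval.
#' @return data frame: stratum, n_values, intermediate_mass; plus attribute
#'   "values" (named list of pooled psi vectors).
#' @export
psi_distribution_by_stratum <- function(psi_matrix, labels,
                                        band = c(0.2, 0.8)) {
  labels <- labels[rownames(psi_matrix)]
  strata <- sort(unique(labels))
  vals <- lapply(strata, function(s) {
    v <- as.vector(psi_matrix[labels == s, , drop = FALSE])
    v[!is.na(v)]
  })
  names(vals) <- strata
  if (any(lengths(vals) == 0)) warnf("empty stratum in psi pooling")
  out <- data.frame(stratum = strata, n_values = lengths(vals),
                    intermediate_mass = vapply(vals, function(v) {
                      if (!length(v)) return(NA_real_)
                      mean(v >= band[1] & v <= band[2])
                    }, numeric(1)))
  rownames(out) <- NULL
  attr(out, "values") <- vals
  out
}

#' Per-event count of patients with tumor/normal differential splicing
#'
#' Applies the three differential-splicing criteria (read support, isoform
#' ratio change, Bayes factor) to each patient's matched tumor/normal pair of
#' counts and counts, per event, the patients called significant. Fully
#' vectorized over the events x patients matrices.
#'
#' @param I_tumor,E_tumor,I_normal,E_normal events x patients count matrices.
#' @param min_reads,min_delta,min_bf the differential-call thresholds.
#' @return integer vector of misspliced-patient counts per event (named by
#'   rownames).
#' @export
per_patient_missplicing <- function(I_tumor, E_tumor, I_normal, E_normal,
                                    min_reads = 20, min_delta = 0.10,
                                    min_bf = 1) {
  n_t <- I_tumor + E_tumor
  n_n <- I_normal + E_normal
  psi_t <- ifelse(n_t > 0, I_tumor / n_t, NA)
  psi_n <- ifelse(n_n > 0, I_normal / n_n, NA)
  bf <- matrix(NA_real_, nrow(I_tumor), ncol(I_tumor))
  ok <- n_t > 0 & n_n > 0
  bf[ok] <- bayes_factor_binomial(I_normal[ok], n_n[ok], I_tumor[ok], n_t[ok])
  sig <- ok & n_t >= min_reads & n_n >= min_reads &
    abs(psi_t - psi_n) >= min_delta & bf >= min_bf
  rowSums(sig, na.rm = TRUE)
}

#' Flag frequently misspliced events and stratum proportions
#'
#' @param patient_counts per-event misspliced-patient counts (named).
#' @param labels named stratum label per event.
#' @param min_patients inclusive flagging threshold.
#' @return list with `flagged` (event ids), `per_stratum` (stratum,
#'   n_events, n_flagged, proportion) and `ratio` (sensitive / insensitive
#'   proportion when those strata exist; otherwise NA).
#' @export
frequent_missplicing <- function(patient_counts, labels, min_patients = 10) {
  flagged <- patient_counts >= min_patients
  labels <- labels[names(patient_counts)]
  strata <- sort(unique(labels))
  per <- data.frame(stratum = strata,
                    n_events = as.integer(table(labels)[strata]),
                    n_flagged = vapply(strata, function(s) sum(flagged[labels == s]),
                                       integer(1)))
  per$proportion <- per$n_flagged / per$n_events
  ratio <- if (all(c("sensitive", "insensitive") %in% strata)) {
    ps <- per$proportion[per$stratum == "sensitive"]
    pi <- per$proportion[per$stratum == "insensitive"]
    if (pi > 0) ps / pi else Inf
  } else NA_real_
  rownames(per) <- NULL
  list(flagged = names(patient_counts)[flagged], per_stratum = per,
       ratio = ratio)
}

#' One-sided Kolmogorov-Smirnov enrichment of missplicing frequency
#'
#' Tests whether snRNA-KD-sensitive events are misspliced in more patients
#' than insensitive events. Both groups' misspliced-patient fractions are
#' turned into empirical CDFs evaluated on the grid {0, 1/n_steps, ..., 1}
#' (the percentage lattice implied by the cohort size);
#' `D+ = max(CDF_insensitive - CDF_sensitive)` and the asymptotic one-sided
#' p-value is `exp(-2 * m_eff * D+^2)` with `m_eff = m1 m2 / (m1 + m2)`.
#' For small groups an exact permutation p-value over all label reassignments
#' is available.
#'
#' @param counts_sensitive,counts_insensitive misspliced-patient counts (or
#'   fractions if `n_patients = 1`) per event.
#' @param n_patients cohort size used to convert counts to fractions.
#' @param n_steps number of CDF evaluation steps (defaults to `n_patients`).
#' @param exact compute the permutation p-value by full enumeration (only
#'   feasible for small groups).
#' @return list with D (D+), p_value, method.
#' @export
ks_enrichment <- function(counts_sensitive, counts_insensitive,
                          n_patients = 107L, n_steps = n_patients,
                          exact = FALSE) {
  if (!length(counts_sensitive) || !length(counts_insensitive)) {
    stopf("both groups must be non-empty")
  }
  fs <- counts_sensitive / n_patients
  fi <- counts_insensitive / n_patients
  grid <- seq(0, 1, length.out = n_steps + 1L)
  dplus <- function(a, b) max(stats::ecdf(b)(grid) - stats::ecdf(a)(grid))
  D <- dplus(fs, fi)
  m1 <- length(fs); m2 <- length(fi)
  if (exact) {
    pool <- c(fs, fi)
    combos <- utils::combn(m1 + m2, m1)
    stat <- apply(combos, 2, function(i) dplus(pool[i], pool[-i]))
    p <- mean(stat >= D - 1e-12)
    method <- "exact permutation"
  } else {
    meff <- m1 * m2 / (m1 + m2)
    p <- min(1, exp(-2 * meff * D^2))
    method <- "asymptotic"
  }
  list(D = D, p_value = p, method = method)
}

#' Psi in the cohort extremes of an snRNA's abundance
#'
#' Ranks cohort samples by the relative abundance of one snRNA and contrasts
#' an event's splicing between the `extreme_n` highest and lowest samples.
#' Ties at either cut are included in full and flagged.
#'
#' @param rel_abundance named per-sample relative abundance of the snRNA.
#' @param psi named per-sample psi of the event.
#' @param n_reads optional named per-sample read support, summed per group.
#' @param extreme_n group size (must not exceed half the cohort).
#' @return list with high (samples, mean_psi, total_reads), low (same),
#'   ties_included.
#' @export
stratify_by_snrna_level <- function(rel_abundance, psi, n_reads = NULL,
                                    extreme_n = 10L) {
  n <- length(rel_abundance)
  if (extreme_n > n %/% 2) stopf("extreme_n exceeds half the cohort")
  ord <- sort(rel_abundance)
  lo_cut <- ord[extreme_n]
  hi_cut <- ord[n - extreme_n + 1L]
  low <- names(rel_abundance)[rel_abundance <= lo_cut]
  high <- names(rel_abundance)[rel_abundance >= hi_cut]
  ties <- length(low) > extreme_n || length(high) > extreme_n
  if (ties) warnf("ties at the abundance cut: including all tied samples")
  grp <- function(s) list(samples = s,
                          mean_psi = mean(psi[s], na.rm = TRUE),
                          total_reads = if (is.null(n_reads)) NA_real_
                          else sum(n_reads[s], na.rm = TRUE))
  list(high = grp(high), low = grp(low), ties_included = ties)
}
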