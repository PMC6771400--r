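#' Estimate qPCR amplification efficiency from a dilution series
#'
#' Fits the least-squares slope m of Ct against log10(dilution factor) and
#' returns the per-cycle amplification efficiency `alpha = 10^(-1/m)`. A
#' perfectly doubling assay (Ct increments of log2(10) ~ 3.3219 per ten-fold
#' dilution) yields alpha = 2.
#'
#' @param dilutions data frame with columns assay, dilution, Ct (one or more
#'   assays), or a numeric Ct vector with `dilution` supplied separately.
#' @param dilution dilution factors when `dilutions` is a bare Ct vector.
#' @return named numeric vector of efficiencies, one per assay. Values outside
#'   (1.6, 2.2] are reported with a warning but not altered.
#' @export
estimate_efficiency <- function(dilutions, dilution = NULL) {
  if (is.numeric(dilutions)) {
    dilutions <- data.frame(assay = "assay", dilution = dilution, Ct = dilutions)
  }
  out <- vapply(split(dilutions, dilutions$assay), function(d) {
    if (nrow(d) < 3) stopf("assay %s: need >= 3 dilution points", d$assay[1])
    if (diff(range(log10(d$dilution))) < 2 - 1e-9) {
      stopf("assay %s: dilution series must span >= 2 orders of magnitude",
            d$assay[1])
    }
    ord <- order(d$dilution, decreasing = TRUE)
    if (is.unsorted(d$Ct[ord])) {
      warnf("assay %s: Ct not monotone in dilution; fit proceeds", d$assay[1])
    }
    m <- stats::coef(stats::lm(Ct ~ log10(dilution), data = d))[[2]]
    if (!is.finite(m) || abs(m) < 1e-9) {
      stopf("assay %s: zero slope, efficiency undefined", d$assay[1])
    }
    10^(-1 / m)
  }, numeric(1))
  bad <- out <= 1.6 | out > 2.2
  if (any(bad)) {
    warnf("efficiency outside (1.6, 2.2] for: %s",
          paste(sprintf("%s (%.3f)", names(out)[bad], out[bad]), collapse = ", "))
  }
  out
}

#' Delta-Ct against the 7SK/7SL/5S pseudoreference
#'
#' Replicate Ct values are averaged per sample x assay first; the
#' pseudoreference is the mean of the averaged reference-assay Cts within each
#' sample, and `delta_ct = Ct_assay - mean(Ct_references)`. Subtracting the
#' within-sample reference mean corrects for variation in RNA input, so adding
#' a constant to all Ct values of a sample leaves delta-Ct unchanged.
#'
#' @param ct data frame with columns sample, assay, replicate, Ct.
#' @param reference_assays assays forming the pseudoreference; every sample
#'   must carry all of them.
#' @return data frame with sample, assay, mean_ct, delta_ct (references
#'   included, their delta-Ct being relative to the same pseudoreference).
#' @export
delta_ct <- function(ct, reference_assays = c("7SK", "7SL", "5S")) {
  stopifnot(all(c("sample", "assay", "Ct") %in% names(ct)))
  if (any(!is.finite(ct$Ct) | ct$Ct <= 0)) stopf("Ct values must be finite and > 0")
  agg <- stats::aggregate(Ct ~ sample + assay, ct, mean)
  names(agg)[3] <- "mean_ct"
  for (s in unique(agg$sample)) {
    have <- agg$assay[agg$sample == s]
    miss <- setdiff(reference_assays, have)
    if (length(miss)) {
      stopf("sample %s is missing reference assay(s): %s", s,
            paste(miss, collapse = ", "))
    }
  }
  refmean <- stats::aggregate(mean_ct ~ sample,
                              agg[agg$assay %in% reference_assays, ], mean)
  names(refmean)[2] <- "ref_ct"
  out <- merge(agg, refmean, by = "sample")
  out$delta_ct <- out$mean_ct - out$ref_ct
  out <- out[order(out$sample, out$assay), c("sample", "assay", "mean_ct", "delta_ct")]
  rownames(out) <- NULL
  out
}

#' Delta-delta-Ct and relative abundance
#'
#' Calibrates delta-Ct values per assay either against the median across all
#' samples (tissue/cohort mode: the per-assay median of the resulting
#' delta-delta-Ct is 0 by construction) or against a named calibrator sample
#' (knockdown mode, e.g. a scrambled-control transfection). Relative abundance
#' is `2^-ddCt`, or the efficiency-corrected `alpha_assay^-ddCt` when
#' per-assay amplification efficiencies are supplied; with alpha = 2
#' throughout, the two coincide.
#'
#' @param dct output of [delta_ct()].
#' @param calibrator `"median"` or a sample identifier.
#' @param alpha optional named per-assay efficiencies.
#' @return `dct` with columns delta_delta_ct and rel_abundance appended.
#' @export
delta_delta_ct <- function(dct, calibrator = "median", alpha = NULL) {
  if (identical(calibrator, "median")) {
    cal <- stats::aggregate(delta_ct ~ assay, dct, stats::median)
  } else {
    if (!calibrator %in% dct$sample) {
      stopf("calibrator sample '%s' absent from the panel", calibrator)
    }
    cal <- dct[dct$sample == calibrator, c("assay", "delta_ct")]
  }
  names(cal)[2] <- "cal_ct"
  out <- merge(dct, cal, by = "assay", sort = FALSE)
  out$delta_delta_ct <- out$delta_ct - out$cal_ct
  a <- if (is.null(alpha)) rep(2, nrow(out)) else {
    if (!all(out$assay %in% names(alpha))) stopf("alpha must name every assay")
    unname(alpha[out$assay])
  }
  out$rel_abundance <- a^-out$delta_delta_ct
  out <- out[order(out$sample, out$assay),
             c("sample", "assay", "mean_ct", "delta_ct", "delta_delta_ct",
               "rel_abundance")]
  rownames(out) <- NULL
  out
}

#' Replicate confidence interval by balanced repeated replication
#'
#' The point estimate is the mean of the technical replicates; its variance is
#' estimated from the spread of half-sample replicate estimates. With an odd
#' replicate count the half-samples are the leave-one-out subsets; with an
#' even count, all subsets of half size. Because a subset of size m carries
#' only (1/m - 1/n) of the estimator variance, the mean squared deviation is
#' rescaled by m/(n - m) — the identity factor for genuine half-samples and
#' the jackknife factor (n - 1) for leave-one-out subsets. The 95% interval
#' is symmetric around the point estimate using Student-t quantiles on
#' n - 1 degrees of freedom: with triplicates the replicate variance is
#' estimated on 2 degrees of freedom, and normal quantiles would give badly
#' anti-conservative intervals.
#'
#' @param values numeric replicate measurements (>= 2; a single replicate
#'   yields an NA interval with a warning).
#' @param conf confidence level.
#' @return list with point, se, ci_low, ci_high, n_halfsamples.
#' @export
replicate_ci_brr <- function(values, conf = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  point <- mean(values)
  if (n < 2) {
    warnf("single replicate: confidence interval undefined")
    return(list(point = point, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n_halfsamples = 0L))
  }
  subsets <- if (n %% 2 == 1) {
    lapply(seq_len(n), function(i) values[-i])
  } else {
    utils::combn(n, n %/% 2, function(i) values[i], simplify = FALSE)
  }
  est <- vapply(subsets, mean, numeric(1))
  m <- length(subsets[[1]])
  v <- m / (n - m) * mean((est - point)^2)
  z <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  list(point = point, se = sqrt(v),
       ci_low = point - z * sqrt(v), ci_high = point + z * sqrt(v),
       n_halfsamples = length(subsets))
}

#' Hierarchical clustering of snRNA panel profiles
#'
#' Agglomerates samples under the Ward.D2 criterion on Euclidean distances of
#' their delta-delta-Ct profiles. The delta-delta-Ct standardization already
#' centers each assay on its calibrator, so no further scaling is applied.
#' Sample x assay cells that are entirely missing are imputed with the assay
#' median and flagged. Rows are ordered lexicographically by sample id before
#' clustering so that tied merges resolve deterministically.
#'
#' @param ddct matrix (samples x assays) of delta-delta-Ct values, or the long
#'   data frame from [delta_delta_ct()].
#' @return list with `hclust`, `order` (sample ids in dendrogram order),
#'   `newick` (the dendrogram as a Newick string) and `imputed`
#'   (sample/assay pairs filled with the assay median).
#' @export
cluster_panel <- function(ddct) {
  if (is.data.frame(ddct)) {
    wide <- stats::reshape(ddct[, c("sample", "assay", "delta_delta_ct")],
                           idvar = "sample", timevar = "assay",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$sample
    colnames(m) <- sub("^delta_delta_ct\\.", "", colnames(m))
    ddct <- m
  }
  if (nrow(ddct) < 2) stopf("clustering needs >= 2 samples")
  ddct <- ddct[order(rownames(ddct)), , drop = FALSE]
  imputed <- which(is.na(ddct), arr.ind = TRUE)
  if (nrow(imputed)) {
    med <- apply(ddct, 2, stats::median, na.rm = TRUE)
    ddct[imputed] <- med[imputed[, 2]]
  }
  dm <- stats::dist(ddct)
  # deterministic tie-break: inflate later (lexicographically greater) pairs
  # by an infinitesimal factor so equal distances merge in sample-id order
  dm <- dm * (1 + 1e-12 * seq_along(dm) / length(dm))
  hc <- stats::hclust(dm, method = "ward.D2")
  nw <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, order = rownames(ddct)[hc$order], newick = nw,
       imputed = if (nrow(imputed)) {
         data.frame(sample = rownames(ddct)[imputed[, 1]],
                    assay = colnames(ddct)[imputed[, 2]])
       } else NULL)
}
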