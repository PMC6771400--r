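#' Simulate a matched tumor/normal patient cohort
#'
#' For every patient x event pair, with probability given by the event's
#' stratum missplicing rate the tumor's true inclusion level is shifted by
#' `delta_psi` relative to the patient-matched normal sample (clamped to
#' [0, 1]); otherwise tumor and normal share the same true value. Junction
#' read counts are then sampled per sample with Poisson depth and a binomial
#' isoform split, exactly as in the single-condition simulator. A two-rate
#' Bernoulli mixture over sensitivity strata generates the contrast the
#' cohort analysis is designed to recover: snRNA-KD-sensitive events
#' misspliced in more patients than insensitive ones.
#'
#' @param n_events number of splicing events.
#' @param n_patients number of matched tumor/normal pairs (>= 2).
#' @param frac_sensitive fraction of events labeled snRNA-sensitive.
#' @param rate_sensitive,rate_insensitive per-patient missplicing
#'   probabilities by stratum, each in [0, 1].
#' @param delta_psi signed true inclusion shift applied to misspliced
#'   tumor/event pairs.
#' @param depth mean informative reads per event per sample.
#' @param psi_base true inclusion in normal tissue, recycled over events.
#' @param subtypes subtype labels cycled over patients.
#' @param seed integer seed.
#' @return list with matrices `I_tumor`, `E_tumor`, `I_normal`, `E_normal`
#'   (events x patients), `psi_tumor`/`psi_normal` truth matrices,
#'   `misspliced` logical truth matrix, `labels` (event_id, label),
#'   and `metadata` (patient, subtype).
#' @export
simulate_cohort <- function(n_events = 500L, n_patients = 107L,
                            frac_sensitive = 0.2,
                            rate_sensitive = 0.3, rate_insensitive = 0.05,
                            delta_psi = 0.3, depth = 200,
                            psi_base = 0.5,
                            subtypes = c("LumA", "LumB", "HER2", "TNBC"),
                            seed = 1L) {
  if (n_patients < 2) stopf("n_patients must be >= 2")
  for (r in c(rate_sensitive, rate_insensitive)) {
    if (r < 0 || r > 1) stopf("missplicing rates must lie in [0, 1]")
  }
  with_seed(seed, {
    event_id <- sprintf("EV%04d", seq_len(n_events))
    n_sens <- round(frac_sensitive * n_events)
    label <- rep(c("sensitive", "insensitive"),
                 c(n_sens, n_events - n_sens))
    rate <- ifelse(label == "sensitive", rate_sensitive, rate_insensitive)
    psi0 <- matrix(rep_len(psi_base, n_events), n_events, n_patients)
    mis <- matrix(stats::rbinom(n_events * n_patients, 1L, rep(rate, n_patients)) == 1L,
                  n_events, n_patients)
    shift <- rep_len(delta_psi, n_events)
    psi_t <- psi0 + ifelse(mis, shift, 0)
    psi_t[] <- pmin(1, pmax(0, psi_t))    # clamp in place to keep dims
    draw <- function(psi) {
      n <- matrix(stats::rpois(length(psi), depth), nrow(psi), ncol(psi))
      I <- matrix(stats::rbinom(length(psi), as.vector(n), as.vector(psi)),
                  nrow(psi), ncol(psi))
      list(n = n, I = I, E = n - I)
    }
    tum <- draw(psi_t); nor <- draw(psi0)
    dn <- list(event_id, sprintf("P%03d", seq_len(n_patients)))
    out <- list(I_tumor = tum$I, E_tumor = tum$E,
                I_normal = nor$I, E_normal = nor$E,
                psi_tumor = psi_t, psi_normal = psi0, misspliced = mis,
                labels = data.frame(event_id = event_id, label = label),
                metadata = data.frame(patient = dn[[2]],
                                      subtype = rep_len(subtypes, n_patients)))
    out[1:7] <- lapply(out[1:7], function(m) { dimnames(m) <- dn; m })
    out
  })
}

#' Simulate per-nucleotide Pol II occupancy tracks over gene bodies
#'
#' Coverage across each gene body is the gene's expression level times a flat
#' per-nucleotide baseline, optionally elevated over designated exons —
#' emulating locally increased polymerase occupancy. Poisson noise is added
#' when `noise = TRUE`. Positions outside gene bodies have zero coverage.
#'
#' @param annotation a [sim_annotation()] result (gene and exon models).
#' @param expression named per-gene expression multiplier (>= 0); unnamed
#'   scalars are recycled.
#' @param elevated named list mapping gene_id to indices of exons (genomic
#'   order, first transcript) whose coverage is multiplied by
#'   `elevation_fold`.
#' @param elevation_fold fold-change applied to designated exons.
#' @param baseline per-nucleotide expected coverage at expression 1.
#' @param noise add Poisson sampling noise to the expected coverage.
#' @param seed integer seed.
#' @return data frame in bedGraph column order (chrom, start, end, value),
#'   0-based half-open, one row per run of constant coverage.
#' @export
simulate_coverage_tracks <- function(annotation, expression = 1,
                                     elevated = list(), elevation_fold = 2,
                                     baseline = 10, noise = FALSE, seed = 1L) {
  genes <- annotation$genes
  expr <- if (is.null(names(expression))) {
    stats::setNames(rep_len(expression, nrow(genes)), genes$gene_id)
  } else expression
  if (!all(names(elevated) %in% genes$gene_id)) {
    stopf("elevated refers to genes absent from the models")
  }
  if (any(expr < 0)) stopf("expression must be >= 0")
  with_seed(seed, {
    rows <- vector("list", nrow(genes))
    for (g in seq_len(nrow(genes))) {
      gid <- genes$gene_id[g]
      ex <- annotation$exons
      ex <- ex[ex$gene_id == gid & ex$transcript_id == paste0(gid, ".t1"), ,
               drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      span <- seq.int(genes$start[g], genes$end[g] - 1L)
      val <- rep(baseline * expr[[gid]], length(span))
      idx <- elevated[[gid]]
      if (length(idx)) {
        for (i in idx) {
          sel <- span >= ex$start[i] & span < ex$end[i]
          val[sel] <- val[sel] * elevation_fold
        }
      }
      if (noise) val <- stats::rpois(length(val), val)
      r <- rle(val)
      ends <- genes$start[g] + cumsum(r$lengths)
      rows[[g]] <- data.frame(chrom = genes$chrom[g],
                              start = ends - r$lengths, end = ends,
                              value = r$values)
    }
    do.call(rbind, rows)
  })
}
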