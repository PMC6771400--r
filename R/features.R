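#' Splice-site scoring models
#'
#' A splice-site model holds a per-position score matrix over A/C/G/T spanning
#' a fixed window around the exon-intron boundary (donor default: 9 nt,
#' positions -3..+6; acceptor default: 23 nt, -20..+3). Scores for a sequence
#' are the sum of per-position entries, so a user-supplied maximum-entropy
#' style score table and the built-in first-order log-odds model trained on
#' annotated sites versus a background share one scoring path.
#'
#' `splice_site_model()` wraps a supplied score table;
#' `train_splice_site_model()` builds the log-odds fallback:
#' log2(p_site / p_background) per position, with a pseudocount on observed
#' frequencies. Under a uniform site model and uniform background every score
#' is 0.
#'
#' @param score_table 4 x window numeric matrix, rows named A, C, G, T.
#' @param kind "donor" or "acceptor".
#' @return object of class `splice_site_model`.
#' @export
splice_site_model <- function(score_table, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(score_table), nrow(score_table) == 4)
  if (is.null(rownames(score_table))) rownames(score_table) <- c("A", "C", "G", "T")
  stopifnot(setequal(rownames(score_table), c("A", "C", "G", "T")),
            all(is.finite(score_table)))
  structure(list(kind = kind, window = ncol(score_table),
                 score_table = score_table[c("A", "C", "G", "T"), , drop = FALSE]),
            class = "splice_site_model")
}

#' @rdname splice_site_model
#' @param site_seqs equal-length training sequences of annotated sites.
#' @param background either background base frequencies (named numeric over
#'   ACGT) or sequences to estimate them from; default uniform.
#' @param pseudocount added to per-position base counts.
#' @export
train_splice_site_model <- function(site_seqs, kind = c("donor", "acceptor"),
                                    background = NULL, pseudocount = 0.5) {
  kind <- match.arg(kind)
  pwm <- build_pwm(site_seqs, pseudocount = pseudocount)
  bg <- if (is.null(background)) {
    c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  } else if (is.character(background)) {
    f <- colSums(Biostrings::letterFrequency(
      Biostrings::DNAStringSet(background), c("A", "C", "G", "T")))
    f / sum(f)
  } else background / sum(background)
  splice_site_model(log2(pwm / bg[rownames(pwm)]), kind = kind)
}

#' Score a sequence under a splice-site model
#'
#' @param sequence character string(s), length equal to the model window,
#'   alphabet ACGT (case-insensitive). Sequences containing other letters get
#'   an NA score with a warning.
#' @param model a [splice_site_model()].
#' @return numeric score(s); the sum of per-position table entries.
#' @export
score_splice_site <- function(sequence, model) {
  stopifnot(inherits(model, "splice_site_model"))
  sequence <- toupper(sequence)
  vapply(sequence, function(s) {
    if (nchar(s) != model$window) {
      stopf("sequence length %d does not match model window %d",
            nchar(s), model$window)
    }
    b <- strsplit(s, "")[[1]]
    if (!all(b %in% c("A", "C", "G", "T"))) {
      warnf("sequence contains non-ACGT bases; score undefined")
      return(NA_real_)
    }
    ri <- match(b, rownames(model$score_table))
    sum(model$score_table[cbind(ri, seq_along(b))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Position weight matrix of aligned sequences
#'
#' @param sequences equal-length sequences over ACGT.
#' @param pseudocount added to each base count per position (default 0, in
#'   which case columns are plain frequencies summing to 1).
#' @return 4 x window matrix of per-position base frequencies.
#' @export
build_pwm <- function(sequences, pseudocount = 0) {
  if (length(sequences) == 0) stopf("no sequences supplied")
  if (length(unique(nchar(sequences))) != 1) stopf("sequences must be equal length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(toupper(sequences)))
  bases <- c("A", "C", "G", "T")
  cnt <- matrix(0, 4, nchar(sequences[1]), dimnames = list(bases, NULL))
  present <- intersect(rownames(cm), bases)
  cnt[present, ] <- cm[present, , drop = FALSE]
  cnt <- cnt + pseudocount
  sweep(cnt, 2, colSums(cnt), "/")
}

#' GC content of a sequence
#'
#' Case-insensitive; N (and other ambiguity codes) are excluded from the
#' denominator. All-ambiguous input yields NA.
#'
#' @param sequence character vector of sequences.
#' @return numeric fraction(s) in [0, 1].
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence))) stopf("empty sequence")
  s <- Biostrings::DNAStringSet(toupper(sequence))
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  ifelse(denom > 0, (f[, "C"] + f[, "G"]) / denom, NA_real_)
}

#' Classify an exon as 5'UTR, CDS, 3'UTR or mixed
#'
#' Strand-aware comparison of the exon interval against the transcript's
#' coding region (genomic 0-based half-open coordinates): an exon entirely on
#' the 5' side of the CDS is 5'UTR, entirely inside is CDS, entirely on the
#' 3' side is 3'UTR, and one straddling a CDS boundary is "mixed".
#' Transcripts without an annotated CDS give "unclassified".
#'
#' @param exon_start,exon_end exon interval.
#' @param cds_start,cds_end coding interval (genomic; NA when absent).
#' @param strand "+" or "-".
#' @param tx_start,tx_end optional transcript span; exons outside it error.
#' @return character label; vectorized over exons.
#' @export
classify_exon_region <- function(exon_start, exon_end, cds_start, cds_end,
                                 strand, tx_start = NULL, tx_end = NULL) {
  n <- length(exon_start)
  if (!is.null(tx_start)) {
    if (any(exon_start < tx_start | exon_end > tx_end)) {
      stopf("exon outside its transcript span")
    }
  }
  strand <- rep_len(strand, n)
  cds_start <- rep_len(cds_start, n); cds_end <- rep_len(cds_end, n)
  left <- exon_end <= cds_start
  right <- exon_start >= cds_end
  inside <- exon_start >= cds_start & exon_end <= cds_end
  out <- ifelse(is.na(cds_start) | is.na(cds_end), "unclassified",
                ifelse(inside, "CDS",
                       ifelse(left, ifelse(strand == "+", "5UTR", "3UTR"),
                              ifelse(right, ifelse(strand == "+", "3UTR", "5UTR"),
                                     "mixed"))))
  out
}

#' Branchpoints serving each exon event
#'
#' For every event, collects the branchpoints of the intron directly upstream
#' (in transcript orientation) of the event region's 5' end — the intron whose
#' 3' splice site is the region start on the plus strand, or the region end on
#' the minus strand — keeping only branchpoints within `window` nt of that 3'
#' splice site (inclusive bound).
#'
#' @param events event catalog (chrom, strand, region_start, region_end).
#' @param branchpoints table with chrom, pos, strand, three_prime_ss, energy.
#' @param window maximum distance to the 3' splice site, nt.
#' @return data frame: event_id, distance, energy (0 rows for events with no
#'   qualifying branchpoint).
#' @export
branchpoint_features <- function(events, branchpoints, window = 200) {
  bp <- branchpoints
  dist <- ifelse(bp$strand == "+", bp$three_prime_ss - bp$pos,
                 bp$pos - bp$three_prime_ss + 1L)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ss <- if (events$strand[i] == "+") events$region_start[i] else events$region_end[i]
    hit <- bp$chrom == events$chrom[i] & bp$strand == events$strand[i] &
      bp$three_prime_ss == ss & dist <= window & dist > 0
    if (!any(hit)) return(NULL)
    data.frame(event_id = events$event_id[i], distance = dist[hit],
               energy = bp$energy[hit])
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(event_id = character(), distance = numeric(),
                      energy = numeric())
}

#' Transcripts per million from counts and effective lengths
#'
#' @param counts per-gene read counts.
#' @param lengths matching effective lengths (> 0), nt.
#' @return named TPM vector summing to 1e6 (NA if all counts are zero).
#' @export
compute_tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stopf("effective lengths must be > 0")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) {
    warnf("zero total count: TPM undefined")
    return(rep(NA_real_, length(counts)))
  }
  rate / tot * 1e6
}

#' Mean per-nucleotide Pol II occupancy per exon
#'
#' Averages a bedGraph-style coverage track over each exon (positions without
#' coverage contribute 0), after removing exons of genes expressed below
#' `min_tpm` — lowly transcribed genes mostly contribute noise to occupancy
#' estimates. Exons extending beyond the track are flagged and their
#' uncovered positions treated as zero.
#'
#' @param coverage data frame chrom, start, end, value (0-based half-open).
#' @param exons data frame with gene_id, chrom, start, end.
#' @param gene_tpm named per-gene TPM.
#' @param min_tpm expression threshold.
#' @return data frame: gene_id, chrom, start, end, occupancy, truncated.
#' @export
polii_exon_occupancy <- function(coverage, exons, gene_tpm, min_tpm = 1) {
  keep <- gene_tpm[exons$gene_id] >= min_tpm
  keep[is.na(keep)] <- FALSE
  ex <- exons[keep, , drop = FALSE]
  if (nrow(ex) == 0) return(cbind(ex, occupancy = numeric(0), truncated = logical(0)))
  occ <- numeric(nrow(ex)); trunc <- logical(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    cv <- coverage[coverage$chrom == ex$chrom[i] &
                     coverage$end > ex$start[i] & coverage$start < ex$end[i], ,
                   drop = FALSE]
    ov <- pmin(cv$end, ex$end[i]) - pmax(cv$start, ex$start[i])
    covered <- sum(ov)
    occ[i] <- sum(ov * cv$value) / (ex$end[i] - ex$start[i])
    trunc[i] <- covered < (ex$end[i] - ex$start[i])
  }
  if (any(trunc)) warnf("%d exon(s) extend beyond the coverage track; uncovered positions count as 0", sum(trunc))
  out <- ex
  out$occupancy <- occ
  out$truncated <- trunc
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum comparison with significance stars
#'
#' @param values_a,values_b numeric value groups (each non-empty).
#' @return list with statistic (W), p_value, stars ("****" for p <= 1e-4,
#'   then "***" 1e-3, "**" 0.01, "*" 0.05, "ns").
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stopf("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  p <- wt$p.value
  stars <- if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else
    if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
  list(statistic = unname(wt$statistic), p_value = p, stars = stars)
}

#' Percentile bootstrap confidence interval for the median
#'
#' @param values numeric sample (>= 2 values).
#' @param n_boot bootstrap resamples (a value below 100 warns).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with median, ci_low, ci_high.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000L, seed = 1L, conf = 0.95) {
  if (length(values) < 2) stopf("need >= 2 values")
  if (n_boot < 100) warnf("n_boot < 100: interval will be unstable")
  with_seed(seed, {
    idx <- matrix(sample.int(length(values), length(values) * n_boot,
                             replace = TRUE), nrow = n_boot)
    meds <- apply(idx, 1, function(i) stats::median(values[i]))
    qs <- stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    list(median = stats::median(values), ci_low = qs[1], ci_high = qs[2])
  })
}
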