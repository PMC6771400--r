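#' Ab initio k-mer enrichment between two sequence groups
#'
#' For every k-mer of the requested lengths, the per-sequence occurrence
#' density (overlapping count / (L - k + 1); raw counts by flag) is compared
#' between the two groups with a two-sample Kolmogorov-Smirnov test, and the
#' log2 enrichment of mean densities is computed with a pseudodensity of
#' 1 / (total scored positions in both groups) guarding against division by
#' zero. Motifs pass when p < `p_threshold` and |log2 enrichment| >
#' `lfc_threshold`; the sign of the enrichment gives the direction (positive:
#' enriched in group A).
#'
#' @param sequences_a,sequences_b character vectors of DNA sequences.
#' @param k_values k-mer lengths to query; lengths exceeding the shortest
#'   sequence are skipped with a warning.
#' @param p_threshold KS p-value cutoff.
#' @param lfc_threshold |log2 enrichment| cutoff.
#' @param mode per-sequence "density" (default) or raw "count" occurrences.
#' @param all_motifs return every motif rather than only the passing ones.
#' @return data frame: motif, k, mean_a, mean_b, log2_enrichment, ks_p,
#'   enriched_in, pass.
#' @export
kmer_enrichment <- function(sequences_a, sequences_b, k_values = c(4L, 5L, 6L),
                            p_threshold = 0.01, lfc_threshold = 1.5,
                            mode = c("density", "count"), all_motifs = FALSE) {
  mode <- match.arg(mode)
  if (!length(sequences_a) || !length(sequences_b)) stopf("both groups must be non-empty")
  sa <- Biostrings::DNAStringSet(toupper(sequences_a))
  sb <- Biostrings::DNAStringSet(toupper(sequences_b))
  min_len <- min(Biostrings::width(sa), Biostrings::width(sb))
  out <- list()
  for (k in k_values) {
    if (k > min_len) {
      warnf("k = %d exceeds the shortest sequence; skipped", k)
      next
    }
    ca <- Biostrings::oligonucleotideFrequency(sa, width = k)
    cb <- Biostrings::oligonucleotideFrequency(sb, width = k)
    pos_a <- Biostrings::width(sa) - k + 1L
    pos_b <- Biostrings::width(sb) - k + 1L
    if (mode == "density") {
      ca <- ca / pos_a
      cb <- cb / pos_b
    }
    eps <- 1 / (sum(pos_a) + sum(pos_b))
    mean_a <- colMeans(ca); mean_b <- colMeans(cb)
    lfc <- log2((mean_a + eps) / (mean_b + eps))
    ks_p <- vapply(seq_len(ncol(ca)), function(j) {
      if (all(ca[, j] == 0) && all(cb[, j] == 0)) return(1)
      suppressWarnings(stats::ks.test(ca[, j], cb[, j]))$p.value
    }, numeric(1))
    out[[as.character(k)]] <- data.frame(
      motif = colnames(ca), k = k, mean_a = unname(mean_a),
      mean_b = unname(mean_b), log2_enrichment = unname(lfc), ks_p = ks_p,
      enriched_in = ifelse(lfc > 0, "a", ifelse(lfc < 0, "b", "none")),
      pass = ks_p < p_threshold & abs(lfc) > lfc_threshold)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(motif = character(), k = integer(), mean_a = numeric(),
                      mean_b = numeric(), log2_enrichment = numeric(),
                      ks_p = numeric(), enriched_in = character(),
                      pass = logical())
  }
  rownames(res) <- NULL
  if (all_motifs) res else res[res$pass, , drop = FALSE]
}

#' Summarized metagene coverage profile
#'
#' Each gene body is divided into `n_bins` near-equal bins; per-nucleotide
#' coverage is averaged within each bin and scaled to per-million mapped
#' reads. Genes in which no bin exceeds `min_bin` scaled coverage are
#' removed as too lowly covered; surviving genes are normalized to their
#' median bin (adjusting for expression level), and the profile is the
#' per-bin median across genes. Minus-strand genes are reversed so bin 1 is
#' always the 5' end.
#'
#' @param coverage_by_gene named list of per-nucleotide coverage vectors (one
#'   per gene, in genomic orientation).
#' @param library_size mapped reads in millions (the per-million scaler).
#' @param strand optional named strand vector ("+"/"-"); default all "+".
#' @param n_bins number of bins per gene.
#' @param min_bin scaled-coverage filter: keep genes whose max bin exceeds it.
#' @return list with `profile` (n_bins medians), `n_genes` used, and
#'   `gene_bins` (the normalized per-gene bin matrix). Empty profile (all
#'   NA) with a warning when every gene is filtered.
#' @export
metagene_profile <- function(coverage_by_gene, library_size, strand = NULL,
                             n_bins = 50L, min_bin = 0.1) {
  if (!length(coverage_by_gene)) stopf("no genes supplied")
  strand <- strand %||% stats::setNames(rep("+", length(coverage_by_gene)),
                                        names(coverage_by_gene))
  bins <- t(vapply(names(coverage_by_gene), function(g) {
    v <- coverage_by_gene[[g]]
    if (identical(unname(strand[g]), "-")) v <- rev(v)
    idx <- ceiling(seq_along(v) / (length(v) / n_bins))
    idx[idx > n_bins] <- n_bins
    as.vector(tapply(v, idx, mean)) / library_size
  }, numeric(n_bins)))
  keep <- apply(bins, 1, max) > min_bin
  if (!any(keep)) {
    warnf("all genes fall below the scaled-coverage filter; empty profile")
    return(list(profile = rep(NA_real_, n_bins), n_genes = 0L,
                gene_bins = bins[0, , drop = FALSE]))
  }
  norm <- bins[keep, , drop = FALSE]
  norm <- norm / apply(norm, 1, stats::median)
  list(profile = apply(norm, 2, stats::median), n_genes = sum(keep),
       gene_bins = norm)
}
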