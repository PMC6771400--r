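#' Simulate a replicated qPCR Ct panel with reference assays and dilutions
#'
#' Generates cycle-threshold values under the standard exponential
#' amplification model: `Ct = base_ct - log_alpha(relative abundance) + noise`,
#' per technical replicate, where alpha is the per-assay amplification
#' efficiency (fold amplification per cycle). The panel always contains the
#' three reference assays (7SK, 7SL, 5S rRNA) at unit relative abundance, and a
#' four-point ten-fold dilution series per assay for efficiency estimation.
#'
#' @param samples character sample identifiers.
#' @param rel_abundance matrix (samples x assays) of true relative abundances,
#'   or NULL for all-1 (references are forced to 1 regardless).
#' @param assays assay names beyond the references.
#' @param alpha per-assay amplification efficiencies in (1, 2], recycled.
#' @param noise_sd replicate noise SD in Ct cycles.
#' @param n_replicates technical replicates per sample x assay.
#' @param base_ct Ct of a unit-abundance template.
#' @param dilutions dilution factors of the efficiency series.
#' @param seed integer seed.
#' @return list with `ct` (sample, assay, replicate, Ct), `dilutions`
#'   (assay, dilution, Ct) and `truth` (sample, assay, rel_abundance, alpha).
#' @export
simulate_qpcr_panel <- function(samples,
                                rel_abundance = NULL,
                                assays = c("U1", "U2", "U4", "U5A", "U6"),
                                alpha = 2,
                                noise_sd = 0.1,
                                n_replicates = 3L,
                                base_ct = 12,
                                dilutions = c(1, 1e-1, 1e-2, 1e-3),
                                seed = 1L) {
  refs <- c("7SK", "7SL", "5S")
  all_assays <- c(refs, setdiff(assays, refs))
  if (!all(refs %in% all_assays)) stopf("panel must include reference assays %s",
                                        paste(refs, collapse = ", "))
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  alpha <- rep_len(alpha, length(all_assays))
  names(alpha) <- all_assays
  if (any(alpha <= 1 | alpha > 2)) stopf("efficiencies alpha must lie in (1, 2]")
  ab <- matrix(1, length(samples), length(all_assays),
               dimnames = list(samples, all_assays))
  if (!is.null(rel_abundance)) {
    ab[, colnames(rel_abundance)] <- rel_abundance[samples, , drop = FALSE]
  }
  ab[, refs] <- 1
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates), assay = all_assays,
                        sample = samples, stringsAsFactors = FALSE)
    grid <- grid[, c("sample", "assay", "replicate")]
    mu <- base_ct - log(ab[cbind(grid$sample, grid$assay)]) / log(alpha[grid$assay])
    grid$Ct <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    dil <- expand.grid(dilution = dilutions, assay = all_assays,
                       stringsAsFactors = FALSE)[, c("assay", "dilution")]
    dil$Ct <- base_ct - log(dil$dilution) / log(alpha[dil$assay]) +
      stats::rnorm(nrow(dil), 0, noise_sd)
    list(ct = grid, dilutions = dil,
         truth = data.frame(sample = rep(samples, each = length(all_assays)),
                            assay = rep(all_assays, length(samples)),
                            rel_abundance = as.vector(t(ab)),
                            alpha = rep(alpha, length(samples))))
  })
}
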