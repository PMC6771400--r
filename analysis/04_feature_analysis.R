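#!/usr/bin/env Rscript
# Stage 4 — cis/trans features of snRNA-responsive events.
#
# Contrasts the KD-responsive (sensitive) cassette exons against the
# unresponsive rest: splice-site strength under a log-odds model trained on
# the annotation, exon GC and length, UTR/CDS location, branchpoint distance
# and energy, gene expression (TPM) and Pol II exon occupancy — each with a
# two-sided Wilcoxon test and bootstrap median intervals. Also runs k-mer
# enrichment between the two exon groups and the metagene coverage profile.

library(snsplice)

cfg <- sim_config(seed = 20240917L, n_genes = 60, read_depth = 150,
                  true_psi = 0.6, effect_subset = 0.25, effect_size = -0.3)
# distal-branchpoint structure for the sensitive genes
set.seed(77L)
sens_genes <- sort(sample(cfg$n_genes, round(cfg$effect_subset * cfg$n_genes)))
ann <- sim_annotation(cfg, bp_distal_genes = sens_genes)
events <- ann$events
genome <- ann$genome

se <- events[events$kind == "SE", ]
se$sensitive <- match(se$gene_id, ann$genes$gene_id) %in% sens_genes
seq_of <- function(start, end) substr(genome, start + 1L, end)

# exon-level features
se$length <- se$region_end - se$region_start
se$gc <- vapply(seq_len(nrow(se)), function(i)
  gc_content(seq_of(se$region_start[i], se$region_end[i])), numeric(1))
tx <- ann$transcripts[match(paste0(se$gene_id, ".t1"), ann$transcripts$transcript_id), ]
se$region <- classify_exon_region(se$region_start, se$region_end,
                                  tx$cds_start, tx$cds_end, se$strand)

# splice-site strength: donor model trained on all annotated 5' splice sites
donor_seq <- vapply(seq_len(nrow(se)), function(i) {
  if (se$strand[i] == "+") seq_of(se$region_end[i] - 3L, se$region_end[i] + 6L)
  else chartr("ACGT", "TGCA", paste(rev(strsplit(seq_of(se$region_start[i] - 6L,
                                                        se$region_start[i] + 3L),
                                                 "")[[1]]), collapse = ""))
}, character(1))
donor_model <- train_splice_site_model(donor_seq, kind = "donor")
se$ss5_score <- score_splice_site(donor_seq, donor_model)

# branchpoints serving the cassette exon's upstream intron
bp <- branchpoint_features(se, ann$branchpoints, window = 200)
bp_med <- tapply(bp$distance, bp$event_id, stats::median)
se$bp_median_dist <- unname(bp_med[se$event_id])

# expression and Pol II occupancy
set.seed(11L)
gene_counts <- rpois(nrow(ann$genes), 800)
gene_len <- ann$genes$end - ann$genes$start
tpm <- setNames(compute_tpm(gene_counts, gene_len), ann$genes$gene_id)
cov <- simulate_coverage_tracks(ann, expression = setNames(tpm / mean(tpm),
                                                           ann$genes$gene_id),
                                seed = 12L)
ex1 <- ann$exons[ann$exons$transcript_id == paste0(ann$exons$gene_id, ".t1"), ]
occ <- polii_exon_occupancy(cov, ex1, tpm, min_tpm = 1)
occ_by_gene <- tapply(occ$occupancy, occ$gene_id, mean)
se$polii <- unname(occ_by_gene[se$gene_id])
se$tpm <- unname(tpm[se$gene_id])
write_tsv_plain(se, "results/event_features.tsv")

# group contrasts with Wilcoxon + bootstrap median CI
contrast <- function(feature) {
  a <- se[[feature]][se$sensitive]; b <- se[[feature]][!se$sensitive]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  w <- compare_groups(a, b)
  ca <- bootstrap_median_ci(a, n_boot = 2000, seed = 21L)
  cb <- bootstrap_median_ci(b, n_boot = 2000, seed = 22L)
  data.frame(feature = feature, median_sensitive = ca$median,
             median_other = cb$median, p = w$p_value, stars = w$stars)
}
tab <- do.call(rbind, lapply(c("ss5_score", "gc", "length",
                               "bp_median_dist", "polii", "tpm"), contrast))
write_tsv_plain(tab, "results/feature_contrasts.tsv")
message(paste(sprintf("%s: %.3g vs %.3g (p=%.3g %s)", tab$feature,
              tab$median_sensitive, tab$median_other, tab$p, tab$stars),
        collapse = "\n"))

# k-mer motifs in sensitive vs other exon sequences
seqs_a <- vapply(which(se$sensitive), function(i)
  seq_of(se$region_start[i], se$region_end[i]), character(1))
seqs_b <- vapply(which(!se$sensitive), function(i)
  seq_of(se$region_start[i], se$region_end[i]), character(1))
km <- kmer_enrichment(seqs_a, seqs_b)
write_tsv_plain(km, "results/kmer_motifs.tsv")
message(nrow(km), " motifs pass p<0.01 & |log2E|>1.5")

# metagene profile over simulated gene-body coverage
cov_by_gene <- lapply(seq_len(nrow(ann$genes)), function(g) {
  v <- rep(0, gene_len[g])
  cc <- cov[cov$start >= ann$genes$start[g] & cov$end <= ann$genes$end[g], ]
  for (r in seq_len(nrow(cc))) {
    v[(cc$start[r] - ann$genes$start[g] + 1L):(cc$end[r] - ann$genes$start[g])] <- cc$value[r]
  }
  v
})
names(cov_by_gene) <- ann$genes$gene_id
prof <- metagene_profile(cov_by_gene, library_size = 1,
                         strand = setNames(ann$genes$strand, ann$genes$gene_id))
write_tsv_plain(data.frame(bin = seq_along(prof$profile),
                           median = prof$profile, n_genes = prof$n_genes),
                "results/metagene_profile.tsv")
message("metagene over ", prof$n_genes, " genes; outputs in results/")
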