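test_that("splice-site scoring follows the per-position table walk", {
  # uniform site model over uniform background scores 0 everywhere
  uni <- train_splice_site_model(c("AAAA", "CCCC", "GGGG", "TTTT"),
                                 kind = "donor", pseudocount = 0)
  # columns built from all four bases equally: log-odds 0 per position
  expect_true(all(abs(uni$score_table) < 1e-12))
  expect_equal(score_splice_site("AAAA", uni), 0)
  # consensus sequence attains the maximal achievable score
  tr <- train_splice_site_model(c("GTAAGT", "GTAAGT", "GTGAGT", "GTAAGC"),
                                kind = "donor")
  cons <- paste(rownames(tr$score_table)[apply(tr$score_table, 2, which.max)],
                collapse = "")
  scores <- vapply(replicate(50, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                                       collapse = "")),
                   score_splice_site, numeric(1), model = tr)
  expect_true(all(score_splice_site(cons, tr) >= scores))
  # supplied table: score equals a hand table-walk on one 9-mer
  set.seed(12)
  tab <- matrix(rnorm(36), 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  mod <- splice_site_model(tab, kind = "donor")
  s <- "GTAAGTCCA"
  hand <- sum(vapply(1:9, function(i) tab[substr(s, i, i), i], numeric(1)))
  expect_equal(score_splice_site(s, mod), hand)
  expect_error(score_splice_site("GTAAG", mod), "window")
  expect_warning(out <- score_splice_site("GTAAGTCCN", mod), "non-ACGT")
  expect_true(is.na(out))
})

test_that("PWMs are per-position frequencies over the alphabet", {
  pwm <- build_pwm(c("AC", "AG"))
  expect_equal(pwm[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unname(pwm["C", 2]), 0.5)
  expect_equal(unname(pwm["G", 2]), 0.5)
  expect_true(all(abs(colSums(pwm) - 1) < 1e-12))
  one_hot <- build_pwm(c("GATTACA", "GATTACA"))
  expect_true(all(one_hot %in% c(0, 1)))
  expect_error(build_pwm(character(0)), "no sequences")
  expect_error(build_pwm(c("AC", "ACG")), "equal length")
})

test_that("GC content is case-insensitive and skips ambiguity codes", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("acgt"), 0.5)
  expect_equal(gc_content("ACGTNN"), 0.5)   # N out of the denominator
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content(""), "empty")
})

test_that("exon region classification is strand-aware", {
  # CDS spans [300, 700)
  expect_equal(classify_exon_region(100, 200, 300, 700, "+"), "5UTR")
  expect_equal(classify_exon_region(100, 200, 300, 700, "-"), "3UTR")
  expect_equal(classify_exon_region(800, 900, 300, 700, "+"), "3UTR")
  expect_equal(classify_exon_region(800, 900, 300, 700, "-"), "5UTR")
  expect_equal(classify_exon_region(400, 500, 300, 700, "+"), "CDS")
  expect_equal(classify_exon_region(250, 350, 300, 700, "+"), "mixed")
  expect_equal(classify_exon_region(100, 200, NA, NA, "+"), "unclassified")
  expect_error(classify_exon_region(100, 200, 300, 700, "+",
                                    tx_start = 150, tx_end = 900),
               "outside")
})

test_that("branchpoint features keep the 200-nt window inclusively", {
  ev <- data.frame(event_id = "e1", chrom = "chr1", strand = "+",
                   region_start = 1000, region_end = 1100)
  bp <- data.frame(chrom = "chr1", pos = 1000 - c(40, 180, 250, 200),
                   strand = "+", three_prime_ss = 1000,
                   energy = c(-20, -25, -30, -22))
  out <- branchpoint_features(ev, bp, window = 200)
  expect_setequal(out$distance, c(40, 180, 200))   # 250 dropped, 200 kept
  # no branchpoints in the upstream intron: zero rows, no error
  none <- branchpoint_features(ev, bp[bp$three_prime_ss == 999, ], window = 200)
  expect_equal(nrow(none), 0L)
  # minus-strand event: the upstream intron's 3' splice site is region_end
  evm <- data.frame(event_id = "m1", chrom = "chr1", strand = "-",
                    region_start = 1000, region_end = 1100)
  bpm <- data.frame(chrom = "chr1", pos = 1100 + c(50, 300) - 1L,
                    strand = "-", three_prime_ss = 1100, energy = c(-20, -21))
  expect_equal(branchpoint_features(evm, bpm, window = 200)$distance, 50)
})

test_that("TPM normalizes by length and sums to one million", {
  tpm <- compute_tpm(c(10, 10), c(1000, 2000))
  expect_equal(tpm, c(2e6 / 3, 1e6 / 3))
  expect_equal(compute_tpm(5, 700), 1e6)
  expect_equal(compute_tpm(c(20, 20), c(1000, 2000)),
               compute_tpm(c(10, 10), c(1000, 2000)))  # scale invariance
  expect_warning(out <- compute_tpm(c(0, 0), c(100, 100)), "undefined")
  expect_true(all(is.na(out)))
  expect_error(compute_tpm(10, 0), "> 0")
})

test_that("Pol II occupancy averages coverage with the TPM filter", {
  cov <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(100L, 200L),
                    value = c(5, 0))
  ex <- data.frame(gene_id = c("g1", "g1", "g2"), chrom = "chr1",
                   start = c(0L, 100L, 0L), end = c(100L, 200L, 100L))
  tpm <- c(g1 = 10, g2 = 0.5)
  occ <- polii_exon_occupancy(cov, ex, tpm)
  expect_equal(nrow(occ), 2L)                 # g2 excluded below 1 TPM
  expect_equal(occ$occupancy, c(5, 0))
  # half covered at 10, half uncovered: mean 5, flagged truncated
  ex2 <- data.frame(gene_id = "g1", chrom = "chr1", start = 50L, end = 150L)
  cov2 <- data.frame(chrom = "chr1", start = 50L, end = 100L, value = 10)
  expect_warning(occ2 <- polii_exon_occupancy(cov2, ex2, tpm), "beyond")
  expect_equal(occ2$occupancy, 5)
  expect_true(occ2$truncated)
})

test_that("group comparison matches the exact rank-sum enumeration", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$stars, "ns")
  expect_gt(same$p_value, 0.5)
  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, oracle_wilcox_p(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(sep$p_value, 0.1)              # 2 of C(6,3) assignments
  # star mapping thresholds
  expect_equal(compare_groups(1:20, 101:120)$stars, "****")
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("group contrast is detected at the simulated GC shift", {
  # included-exon GC 0.54 vs excluded 0.46 in expectation, n = 200 per group
  gc_a <- with_seed_for_test(71, vapply(seq_len(200), function(i)
    gc_content(snsplice:::sim_dna(150, 0.54)), numeric(1)))
  gc_b <- with_seed_for_test(72, vapply(seq_len(200), function(i)
    gc_content(snsplice:::sim_dna(150, 0.46)), numeric(1)))
  expect_lt(compare_groups(gc_a, gc_b)$p_value, 0.01)
})

test_that("bootstrap median intervals are valid and calibrated", {
  cc <- bootstrap_median_ci(rep(3.3, 10), n_boot = 500, seed = 1)
  expect_equal(cc$ci_low, cc$ci_high)
  set.seed(5)
  v <- rnorm(40)
  ci <- bootstrap_median_ci(v, n_boot = 2000, seed = 2)
  expect_true(ci$ci_low <= ci$median && ci$median <= ci$ci_high)
  expect_warning(bootstrap_median_ci(v, n_boot = 50, seed = 1), "unstable")
  # coverage of the true median 0 across 500 Normal(0,1) samples of size 50
  cover <- with_seed_for_test(90, vapply(seq_len(500), function(i) {
    x <- rnorm(50)
    ci <- bootstrap_median_ci(x, n_boot = 1000, seed = i)
    ci$ci_low <= 0 && 0 <= ci$ci_high
  }, logical(1)))
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("k-mer enrichment finds planted motifs with correct sign", {
  a <- rep("ACGTACGTACGT", 8)
  b <- rep("TTTTTTTTTTTT", 8)
  res <- kmer_enrichment(a, b, k_values = 4)
  expect_true("ACGT" %in% res$motif[res$enriched_in == "a"])
  expect_true("TTTT" %in% res$motif[res$enriched_in == "b"])
  # identical groups: nothing passes
  expect_equal(nrow(kmer_enrichment(a, a, k_values = 4)), 0L)
  expect_warning(kmer_enrichment("ACG", "ACT", k_values = 4), "skipped")
  expect_error(kmer_enrichment(character(0), "ACGT"), "non-empty")
})

test_that("k-mer KS p-values match exact enumeration on 3-vs-3 input", {
  a <- c("ACGTACGTAAAA", "ACGTAAAAACGT", "AAACGTACGTAC")
  b <- c("TTTGGGTTTGGG", "GGGTTTGGGTTT", "TGTGTGGGTTTG")
  res <- kmer_enrichment(a, b, k_values = 4, all_motifs = TRUE)
  row <- res[res$motif == "ACGT", ]
  da <- vapply(a, function(s) {
    sum(gregexpr("ACGT", s)[[1]] > 0) / (nchar(s) - 3)
  }, numeric(1))
  db <- vapply(b, function(s) {
    hits <- gregexpr("ACGT", s)[[1]]
    sum(hits > 0) / (nchar(s) - 3)
  }, numeric(1))
  # two-sided exact KS by enumeration of all C(6,3) label assignments
  dstat <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(g) - stats::ecdf(y)(g)))
  }
  obs <- dstat(da, db)
  combos <- utils::combn(6, 3)
  pool <- c(da, db)
  stat <- apply(combos, 2, function(i) dstat(pool[i], pool[-i]))
  expect_equal(row$ks_p, mean(stat >= obs - 1e-12))
})

test_that("label permutation passes almost no motifs across seeds", {
  pool <- with_seed_for_test(61, vapply(seq_len(60), function(i)
    snsplice:::sim_dna(80, 0.5), character(1)))
  frac <- vapply(1:3, function(s) {
    idx <- with_seed_for_test(200 + s, sample(60, 30))
    res <- kmer_enrichment(pool[idx], pool[-idx], k_values = c(4L, 5L),
                           all_motifs = TRUE)
    mean(res$pass)
  }, numeric(1))
  expect_true(all(frac < 0.01))
})

test_that("metagene profiles are median-normalized and filtered", {
  # uniform-coverage genes: all 50 bins exactly 1
  genes <- list(g1 = rep(5, 200), g2 = rep(2, 100))
  prof <- metagene_profile(genes, library_size = 1)
  expect_equal(prof$profile, rep(1, 50))
  expect_equal(prof$n_genes, 2L)
  # 100-nt gene into 50 bins: each bin spans exactly 2 nt
  g <- list(g1 = rep(c(1, 3), 50))
  expect_equal(metagene_profile(g, 1)$gene_bins[1, ], rep(1, 50),
               ignore_attr = TRUE)
  # gene whose best scaled bin is 0.05 is excluded by the 0.1 filter
  low <- list(keep = rep(10, 100), drop = rep(0.05, 100))
  expect_equal(metagene_profile(low, library_size = 1)$n_genes, 1L)
  expect_warning(out <- metagene_profile(list(g = rep(0.01, 50)), 1), "filter")
  expect_equal(out$n_genes, 0L)
  # global coverage scaling cancels in the median normalization
  set.seed(8)
  noisy <- list(a = runif(300, 1, 3), b = runif(240, 2, 6), c = runif(520, 1, 9))
  p1 <- metagene_profile(noisy, library_size = 1)
  p2 <- metagene_profile(lapply(noisy, `*`, 7), library_size = 1)
  expect_equal(p1$profile, p2$profile)
  # minus-strand genes are reversed to 5'->3'
  asym <- list(m = c(rep(10, 50), rep(1, 50)))
  pm <- metagene_profile(asym, 1, strand = c(m = "-"))
  pp <- metagene_profile(asym, 1, strand = c(m = "+"))
  expect_equal(pm$profile, rev(pp$profile))
})

test_that("programmed distal branchpoints have larger distances than controls", {
  cfg <- sim_config(seed = 77, n_genes = 30)
  ann <- sim_annotation(cfg, bp_distal_genes = 1:15)
  bp <- ann$branchpoints
  distal <- bp$distance[bp$gene_id %in% sprintf("G%04d", 1:15)]
  ctrl <- bp$distance[!bp$gene_id %in% sprintf("G%04d", 1:15)]
  expect_gt(stats::median(distal), stats::median(ctrl))
  expect_true(all(distal > 100))
})
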