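test_that("catalog derivation recovers SE, RI and competing-site events", {
  # E1-E2-E3 vs E1-E3: one cassette exon
  cat_se <- build_event_catalog(toy_exons("SE"))
  se <- cat_se$events[cat_se$events$kind == "SE", ]
  expect_equal(nrow(se), 1L)
  expect_equal(se$inclusion_keys, "chr1:200-300:+;chr1:400-500:+")
  expect_equal(se$exclusion_keys, "chr1:200-500:+")
  # spliced vs intron-kept: one retained intron
  cat_ri <- build_event_catalog(toy_exons("RI"))
  ri <- cat_ri$events[cat_ri$events$kind == "RI", ]
  expect_equal(nrow(ri), 1L)
  expect_equal(ri$inclusion_keys, "chr1:200:5p:+;chr1:300:3p:+")
  expect_equal(ri$exclusion_keys, "chr1:200-300:+")
  # competing acceptor on the plus strand
  a3 <- data.frame(gene_id = "g1", transcript_id = rep(c("t1", "t2"), each = 2),
                   chrom = "chr1", strand = "+",
                   start = c(100, 300, 100, 340), end = c(200, 400, 200, 400))
  cat_a3 <- build_event_catalog(a3)
  ev <- cat_a3$events[cat_a3$events$kind == "A3SS", ]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$inclusion_keys, "chr1:200-300:+")   # extension isoform
  expect_equal(ev$exclusion_keys, "chr1:200-340:+")
  # same structure on the minus strand is a competing donor
  a5 <- a3; a5$strand <- "-"
  expect_equal(build_event_catalog(a5)$events$kind[1], "A5SS")
  expect_error(build_event_catalog(transform(a3, strand = c("+", "+", "-", "-"))),
               "mixed strands")
})

test_that("novel junction candidates enumerate donors x acceptors", {
  ex <- data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                   strand = "+", start = c(0, 200, 400, 600),
                   end = c(100, 300, 500, 700))
  cat_ <- build_event_catalog(ex)
  expect_equal(nrow(cat_$novel_junctions), 9L)     # 3 donors x 3 acceptors
  expect_equal(sort(unique(cat_$novel_junctions$donor)), c(100, 300, 500))
})

test_that("generator truth and derived catalog agree on every gene", {
  cfg <- sim_config(seed = 19, n_genes = 24)
  ann <- sim_annotation(cfg)
  derived <- build_event_catalog(ann$exons)$events
  m <- merge(ann$events, derived, by = c("inclusion_keys", "exclusion_keys"))
  expect_equal(nrow(m), nrow(ann$events))
  expect_true(all(m$kind.x == m$kind.y))
})

test_that("junction counting honours overhang, gap matching and filters", {
  catalog <- build_event_catalog(toy_exons("SE"))$events
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000")
  rec <- function(pos, cigar, flag = 0, mapq = 50, qname = "r") {
    sprintf("%s\t%d\tchr1\t%d\t%d\t%s\t*\t0\t0\t*\t*", qname, flag, pos, mapq, cigar)
  }
  sam <- c(hdr,
           rec(171, "30M100N37M"),       # spans 200-300 junction, 30/37 anchors
           rec(196, "5M100N62M"),        # 5 nt anchor: excluded
           rec(101, "67M"),              # no gap
           rec(171, "30M100N37M", flag = 256),   # secondary: dropped
           rec(171, "30M100N37M", mapq = 0),     # mapq 0: dropped
           "short\tmalformed")
  got <- count_junction_reads(sam, catalog, min_overhang = 6)
  expect_equal(got$junctions$count, 1L)
  expect_equal(got$junctions$donor, 200L)
  expect_equal(got$junctions$acceptor, 300L)
  expect_equal(got$n_skipped, 1L)
  # TSV/count-table mode passes through unchanged
  tbl <- list(junctions = data.frame(chrom = "chr1", donor = 200L,
                                     acceptor = 300L, strand = "+", count = 7L),
              boundaries = NULL)
  expect_equal(count_junction_reads(tbl, catalog)$junctions$count, 7L)
})

test_that("counting matches brute-force per-read inspection on crafted reads", {
  cfg <- sim_config(seed = 31, n_genes = 6)
  ann <- sim_annotation(cfg)
  cts <- simulate_condition_counts(ann$events, 0.4, 6, seed = 32)
  sam <- tempfile(fileext = ".sam")
  write_sam(cts, c(chr1 = nchar(ann$genome)), sam)
  lines <- readLines(sam)
  expect_lte(sum(!startsWith(lines, "@")), 80)
  got <- count_junction_reads(sam, ann$events)
  want <- oracle_count_sam(lines, catalog_boundaries_for_test(ann$events))
  gk <- setNames(got$junctions$count,
                 paste0(got$junctions$chrom, ":", got$junctions$donor, "-",
                        got$junctions$acceptor, ":", got$junctions$strand))
  expect_equal(gk[names(want$junctions)], setNames(as.integer(want$junctions),
                                                   names(want$junctions)))
  expect_equal(sum(got$junctions$count), sum(want$junctions))
  if (nrow(got$boundaries)) {
    bk <- setNames(got$boundaries$count,
                   paste0(got$boundaries$chrom, ":", got$boundaries$boundary_pos,
                          ":", got$boundaries$side, ":", got$boundaries$strand))
    expect_equal(sum(bk), sum(want$boundaries))
  }
})

test_that("psi follows the per-kind inclusion/exclusion arithmetic", {
  catalog <- build_event_catalog(toy_exons("SE"))$events
  se <- catalog[catalog$kind == "SE", ]
  mk <- function(up, down, skip) {
    list(junctions = data.frame(chrom = "chr1",
                                donor = c(200L, 400L, 200L),
                                acceptor = c(300L, 500L, 500L),
                                strand = "+", count = c(up, down, skip)),
         boundaries = NULL)
  }
  p1 <- estimate_psi(mk(30, 30, 10), se)
  expect_equal(c(p1$I, p1$E, p1$psi, p1$n), c(30, 10, 0.75, 40))
  # stated averaging rule for unequal inclusion support
  p2 <- estimate_psi(mk(20, 40, 10), se)
  expect_equal(c(p2$I, p2$psi), c(30, 0.75))
  p3 <- estimate_psi(mk(20, 40, 10), se, average = "sum")
  expect_equal(p3$I, 60)
  # RI with empty boundaries and junction support: fully spliced
  cat_ri <- build_event_catalog(toy_exons("RI"))$events
  ri <- cat_ri[cat_ri$kind == "RI", ]
  cri <- list(junctions = data.frame(chrom = "chr1", donor = 200L,
                                     acceptor = 300L, strand = "+", count = 50L),
              boundaries = NULL)
  pri <- estimate_psi(cri, ri)
  expect_equal(pri$psi, 0)
  # no reads at all: psi undefined, not an error
  p0 <- estimate_psi(list(junctions = empty_counts(), boundaries = NULL), se)
  expect_true(is.na(p0$psi))
  expect_equal(p0$n, 0)
})

test_that("inclusion and exclusion views of the same counts are conserved", {
  catalog <- build_event_catalog(toy_exons("SE"))$events
  se <- catalog[catalog$kind == "SE", ]
  flipped <- se
  flipped$inclusion_keys <- se$exclusion_keys
  flipped$exclusion_keys <- se$inclusion_keys
  cts <- list(junctions = data.frame(chrom = "chr1",
                                     donor = c(200L, 400L, 200L),
                                     acceptor = c(300L, 500L, 500L),
                                     strand = "+", count = c(12L, 12L, 30L)),
              boundaries = NULL)
  psi_in <- estimate_psi(cts, se)$psi
  psi_ex <- estimate_psi(cts, flipped)$psi
  expect_equal(psi_in + psi_ex, 1)
})

test_that("estimates track simulated truth within binomial error at depth 500", {
  cfg <- sim_config(seed = 41, n_genes = 300)
  ann <- sim_annotation(cfg)
  psis <- with_seed_for_test(42, stats::runif(nrow(ann$events), 0.05, 0.95))
  cts <- simulate_condition_counts(ann$events, psis, 500, seed = 43)
  est <- estimate_psi(cts, ann$events)
  se3 <- 3 * sqrt(psis * (1 - psis) / pmax(est$n, 1))
  ok <- abs(est$psi - psis) <= se3
  expect_gte(mean(ok), 0.99)
})

test_that("flipping every strand leaves psi untouched", {
  cfg <- sim_config(seed = 51, n_genes = 10)
  ann <- sim_annotation(cfg)
  cts <- simulate_condition_counts(ann$events, 0.6, 300, seed = 52)
  sam <- tempfile(fileext = ".sam")
  write_sam(cts, c(chr1 = nchar(ann$genome)), sam)
  psi1 <- estimate_psi(count_junction_reads(sam, ann$events), ann$events)
  # flip only the strand character that terminates each key, not the
  # donor-acceptor dash inside junction coordinates
  flip_keys <- function(s) vapply(strsplit(s, ";", fixed = TRUE), function(k) {
    paste(paste0(substr(k, 1, nchar(k) - 1),
                 chartr("+-", "-+", substring(k, nchar(k)))), collapse = ";")
  }, character(1))
  ev2 <- ann$events
  ev2$strand <- chartr("+-", "-+", ev2$strand)
  ev2$inclusion_keys <- flip_keys(ev2$inclusion_keys)
  ev2$exclusion_keys <- flip_keys(ev2$exclusion_keys)
  lines <- readLines(sam)
  body <- !startsWith(lines, "@")
  f <- strsplit(lines[body], "\t", fixed = TRUE)
  lines[body] <- vapply(f, function(x) {
    x[2] <- as.character(bitwXor(as.integer(x[2]), 16L))
    paste(x, collapse = "\t")
  }, character(1))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(lines, sam2)
  psi2 <- estimate_psi(count_junction_reads(sam2, ev2), ev2)
  expect_equal(psi2$psi, psi1$psi)
  expect_equal(psi2$n, psi1$n)
})

test_that("estimator concordance behaves at the limits", {
  a <- data.frame(event_id = paste0("e", 1:10), psi = seq(0.05, 0.95, length.out = 10))
  expect_equal(estimator_concordance(a, a)$r, 1)
  b <- a; b$psi <- 1 - a$psi
  expect_equal(estimator_concordance(a, b)$r, -1)
  set.seed(7)
  big <- data.frame(event_id = paste0("e", 1:1000), psi = runif(1000))
  big2 <- data.frame(event_id = paste0("e", 1:1000), psi = runif(1000))
  expect_lt(abs(estimator_concordance(big, big2)$r), 0.1)
  expect_warning(out <- estimator_concordance(a[1:2, ], a[1:2, ]), "fewer than 3")
  expect_true(is.na(out$r))
})
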