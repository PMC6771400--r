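#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator: gene and
#' event structure, sequencing depth, true inclusion levels, knockdown effect
#' structure, ASO dose series, cohort design and qPCR panel parameters. The
#' defaults describe the study conditions the pipeline is exercised under:
#' stranded single-end short-read junction counts with Poisson event depth and
#' a binomial isoform split, a subset of events sensitive to snRNA depletion
#' with a dose-dependent monotone shift in inclusion, a patient cohort with
#' matched tumor/normal pairs, and a triplicated qPCR panel with the
#' 7SK/7SL/5S reference assays.
#'
#' @param seed integer seed; identical configurations are guaranteed to yield
#'   byte-identical outputs.
#' @param n_genes number of simulated genes (one alternative event per gene).
#' @param exons_per_gene integer range (min, max) of exons per gene; genes
#'   carrying a cassette exon always have at least 3 exons.
#' @param event_mix named proportions over event kinds SE, RI, A5SS, A3SS;
#'   must sum to 1.
#' @param read_depth mean number of informative reads per event (Poisson).
#' @param true_psi default true inclusion level per event, in [0, 1]; either a
#'   single value or one per gene.
#' @param effect_subset fraction of events designated snRNA-sensitive.
#' @param effect_size delta-psi applied to sensitive events upon knockdown.
#' @param doses ascending ASO amounts (pmol) for the dose-response series.
#' @param cohort list with n_patients, subtypes (labels recycled over
#'   patients), missplicing_rate_sensitive, missplicing_rate_insensitive and
#'   cohort_delta_psi.
#' @param qpcr list with assays, true relative abundances, per-assay
#'   amplification efficiencies alpha in (1, 2], replicate noise SD (Ct
#'   cycles) and replicate count.
#' @param exon_len,intron_len integer ranges (nt) for feature lengths.
#' @param gc_exon,gc_intron expected GC fraction of exonic and intronic
#'   sequence.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = c(3L, 5L),
                       event_mix = c(SE = 0.5, RI = 0.2, A5SS = 0.15, A3SS = 0.15),
                       read_depth = 50,
                       true_psi = 0.5,
                       effect_subset = 0.2,
                       effect_size = -0.3,
                       doses = c(50, 100, 150, 200, 250),
                       cohort = list(n_patients = 107L,
                                     subtypes = c("LumA", "LumB", "HER2", "TNBC"),
                                     missplicing_rate_sensitive = 0.3,
                                     missplicing_rate_insensitive = 0.05,
                                     cohort_delta_psi = 0.3),
                       qpcr = list(assays = c("U1", "U2", "U4", "U5A", "U6"),
                                   rel_abundance = NULL,
                                   alpha = 2,
                                   noise_sd = 0.1,
                                   n_replicates = 3L),
                       exon_len = c(80L, 200L),
                       intron_len = c(250L, 450L),
                       gc_exon = 0.5,
                       gc_intron = 0.4) {
  kinds <- c("SE", "RI", "A5SS", "A3SS")
  if (!setequal(names(event_mix), kinds)) {
    stopf("event_mix must be named proportions over %s", paste(kinds, collapse = ", "))
  }
  event_mix <- event_mix[kinds]
  if (any(event_mix < 0) || abs(sum(event_mix) - 1) > 1e-8) {
    stopf("event_mix proportions must be non-negative and sum to 1")
  }
  if (n_genes < 1) stopf("n_genes must be >= 1")
  if (any(true_psi < 0 | true_psi > 1)) stopf("true_psi must lie in [0, 1]")
  if (effect_subset < 0 || effect_subset > 1) stopf("effect_subset must lie in [0, 1]")
  if (is.unsorted(doses, strictly = TRUE)) stopf("doses must be strictly ascending")
  if (any(exon_len <= 0) || any(intron_len <= 0)) stopf("feature lengths must be positive")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 event_mix = event_mix, read_depth = read_depth,
                 true_psi = true_psi, effect_subset = effect_subset,
                 effect_size = effect_size, doses = doses, cohort = cohort,
                 qpcr = qpcr, exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 gc_exon = gc_exon, gc_intron = gc_intron),
            class = "sim_config")
}

# Random DNA of given length and expected GC fraction.
sim_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# Deterministic assignment of event kinds to genes by largest remainder.
assign_kinds <- function(n, mix) {
  base <- floor(mix * n)
  rem <- mix * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  rep(names(mix), times = base)
}

#' Generate a toy genome, gene models, event catalog and branchpoints
#'
#' Builds `n_genes` multi-exon genes on alternating strands along a single
#' synthetic chromosome, each carrying one designated alternative-splicing
#' unit (cassette exon, retained intron, or competing 5'/3' splice site)
#' expressed as a pair of transcript structures. Exonic and intronic sequence
#' is sampled with separately controllable GC content, a coding region is
#' assigned per gene, and every intron receives 0-3 branchpoints with synthetic
#' pairing energies at bounded distances from its 3' splice site.
#'
#' All coordinates are 0-based, half-open (BED convention). Junctions are keyed
#' genomically by (chrom, intron-left, intron-right, strand).
#'
#' @param config a [sim_config()].
#' @param bp_distal_genes optional integer vector of gene indices whose
#'   branchpoints are placed distally (distance to the 3' splice site in
#'   (100, 200] nt); all other introns draw distances in [15, 100].
#' @param bp_max_dist upper bound (nt, inclusive) on branchpoint distance to
#'   the 3' splice site.
#' @return list with `genome` (named character, one chromosome),
#'   `genes`, `transcripts`, `exons`, `events`, `branchpoints` data frames and
#'   the `config` used. `events` is the ground-truth catalog with
#'   semicolon-joined inclusion/exclusion junction (or boundary) keys.
#' @export
sim_annotation <- function(config, bp_distal_genes = integer(0), bp_max_dist = 200L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    n <- config$n_genes
    kinds <- assign_kinds(n, config$event_mix)
    strands <- rep(c("+", "-"), length.out = n)
    chrom <- "chr1"
    spacer <- 100L

    ex_rows <- vector("list", n)       # per-gene exon tables (both transcripts)
    tx_rows <- vector("list", n)
    ev_rows <- vector("list", n)
    bp_rows <- vector("list", n)
    gene_rows <- vector("list", n)
    seq_chunks <- vector("list", n)
    cursor <- 0L

    for (g in seq_len(n)) {
      kind <- kinds[g]
      strand <- strands[g]
      k <- if (kind %in% c("SE")) {
        max(3L, sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L))
      } else {
        max(2L, sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L))
      }
      elens <- sample(seq(config$exon_len[1], config$exon_len[2]), k, replace = TRUE)
      ilens <- sample(seq(config$intron_len[1], config$intron_len[2]), k - 1L, replace = TRUE)

      gstart <- cursor + spacer
      starts <- integer(k); ends <- integer(k)
      pos <- gstart
      for (i in seq_len(k)) {
        starts[i] <- pos; ends[i] <- pos + elens[i]
        pos <- ends[i] + if (i < k) ilens[i] else 0L
      }
      gend <- ends[k]
      gene_id <- sprintf("G%04d", g)
      m <- max(1L, ceiling(k / 2))             # focal exon / intron index

      # Two transcript structures realizing the designated event kind.
      t1 <- cbind(starts, ends)                 # inclusion / long / spliced form
      if (kind == "SE") {
        t2 <- t1[-m, , drop = FALSE]
        region <- c(starts[m], ends[m])
        inc <- c(junction_key(chrom, ends[m - 1L], starts[m], strand),
                 junction_key(chrom, ends[m], starts[m + 1L], strand))
        exc <- junction_key(chrom, ends[m - 1L], starts[m + 1L], strand)
      } else if (kind == "RI") {
        mi <- min(m, k - 1L)                    # retained intron index
        t2 <- t1
        t2[mi, 2] <- t1[mi + 1L, 2]             # merge flanking exons
        t2 <- t2[-(mi + 1L), , drop = FALSE]
        region <- c(ends[mi], starts[mi + 1L])
        side5 <- if (strand == "+") "5p" else "3p"
        side3 <- if (strand == "+") "3p" else "5p"
        inc <- c(boundary_key(chrom, ends[mi], side5, strand),
                 boundary_key(chrom, starts[mi + 1L], side3, strand))
        exc <- junction_key(chrom, ends[mi], starts[mi + 1L], strand)
      } else {                                  # A5SS / A3SS
        ji <- min(m, k - 1L)                    # intron whose boundary varies
        delta <- sample(25:60, 1L)
        vary_left <- (kind == "A5SS") == (strand == "+")
        t2 <- t1
        if (vary_left) {                        # upstream exon end varies
          t2[ji, 2] <- t1[ji, 2] - delta        # short isoform
          region <- c(t2[ji, 2], t1[ji, 2])
          inc <- junction_key(chrom, t1[ji, 2], starts[ji + 1L], strand)
          exc <- junction_key(chrom, t2[ji, 2], starts[ji + 1L], strand)
        } else {                                # downstream exon start varies
          t2[ji + 1L, 1] <- t1[ji + 1L, 1] + delta
          region <- c(t1[ji + 1L, 1], t2[ji + 1L, 1])
          inc <- junction_key(chrom, ends[ji], t1[ji + 1L, 1], strand)
          exc <- junction_key(chrom, ends[ji], t2[ji + 1L, 1], strand)
        }
      }

      tx1 <- paste0(gene_id, ".t1"); tx2 <- paste0(gene_id, ".t2")
      ex_rows[[g]] <- data.frame(
        gene_id = gene_id,
        transcript_id = c(rep(tx1, nrow(t1)), rep(tx2, nrow(t2))),
        chrom = chrom, strand = strand,
        start = c(t1[, 1], t2[, 1]), end = c(t1[, 2], t2[, 2]))

      cds_start <- starts[1] + elens[1] %/% 2L
      cds_end <- ends[k] - elens[k] %/% 2L
      tx_rows[[g]] <- data.frame(
        transcript_id = c(tx1, tx2), gene_id = gene_id,
        cds_start = cds_start, cds_end = cds_end)
      gene_rows[[g]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                   strand = strand, start = gstart, end = gend,
                                   n_introns = k - 1L, kind = kind)
      ev_rows[[g]] <- data.frame(
        event_id = sprintf("%s.%s", gene_id, kind), kind = kind,
        gene_id = gene_id, chrom = chrom, strand = strand,
        region_start = region[1], region_end = region[2],
        inclusion_keys = paste(inc, collapse = ";"),
        exclusion_keys = exc)

      # Branchpoints: 0-3 per intron, within bp_max_dist of the 3' splice site.
      if (k > 1L) {
        nb <- sample(0:3, k - 1L, replace = TRUE)
        tot <- sum(nb)
        if (tot > 0) {
          intron_idx <- rep(seq_len(k - 1L), nb)
          dist_rng <- if (g %in% bp_distal_genes) c(101L, bp_max_dist) else c(15L, min(100L, bp_max_dist))
          d <- sample(seq(dist_rng[1], dist_rng[2]), tot, replace = TRUE)
          d <- pmin(d, ilens[intron_idx] - 5L)
          three_ss <- if (strand == "+") starts[intron_idx + 1L] else ends[intron_idx]
          bp_pos <- if (strand == "+") three_ss - d else three_ss + d - 1L
          bp_rows[[g]] <- data.frame(chrom = chrom, pos = bp_pos, strand = strand,
                                     three_prime_ss = three_ss, distance = d,
                                     energy = round(stats::rnorm(tot, -25, 5), 2),
                                     gene_id = gene_id)
        }
      }

      # Sequence: spacer + alternating exon/intron chunks with set GC.
      chunk_lens <- c(spacer, as.vector(rbind(elens, c(ilens, NA)))[seq_len(2L * k - 1L)])
      chunk_gc <- c(0.4, rep(c(config$gc_exon, config$gc_intron), length.out = 2L * k - 1L))
      seq_chunks[[g]] <- paste(mapply(sim_dna, chunk_lens, chunk_gc), collapse = "")
      cursor <- gend
    }

    genome <- paste0(paste(unlist(seq_chunks), collapse = ""),
                     sim_dna(spacer, 0.4))
    names(genome) <- chrom
    list(config = config,
         genome = genome,
         genes = do.call(rbind, gene_rows),
         transcripts = do.call(rbind, tx_rows),
         exons = do.call(rbind, ex_rows),
         events = do.call(rbind, ev_rows),
         branchpoints = do.call(rbind, bp_rows) %||%
           data.frame(chrom = character(), pos = integer(), strand = character(),
                      three_prime_ss = integer(), distance = integer(),
                      energy = numeric(), gene_id = character()))
  })
}
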