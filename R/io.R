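# Plain-text writers. All outputs are deterministic byte-for-byte given the
# same inputs: fixed column orders, no row names, "." decimal, LF endings.

#' Write a data frame as plain TSV
#' @param df data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tsv_plain <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(file)
}

#' Read a plain TSV written by [write_tsv_plain()]
#' @param file path.
#' @return data frame.
#' @export
read_tsv_plain <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a genome as FASTA
#' @param genome named character vector of sequences.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_genome_fasta <- function(genome, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), file)
  invisible(file)
}

#' Write gene models as GTF
#'
#' Emits exon and CDS features with gene_id/transcript_id attributes,
#' converting the internal 0-based half-open coordinates to GTF's 1-based
#' inclusive convention.
#'
#' @param annotation a [sim_annotation()] result (or any list with `exons`
#'   and `transcripts` tables).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gtf <- function(annotation, file) {
  ex <- annotation$exons
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                      ex$gene_id, ex$transcript_id)
  lines <- sprintf("%s\tsnsplice\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, ex$start + 1L, ex$end, ex$strand, attr_str)
  tx <- annotation$transcripts
  if (!is.null(tx) && all(c("cds_start", "cds_end") %in% names(tx))) {
    cds <- tx[!is.na(tx$cds_start), , drop = FALSE]
    if (nrow(cds)) {
      g <- annotation$genes[match(cds$gene_id, annotation$genes$gene_id), ]
      lines <- c(lines,
                 sprintf('%s\tsnsplice\tCDS\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                         g$chrom, cds$cds_start + 1L, cds$cds_end, g$strand,
                         cds$gene_id, cds$transcript_id))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read exon models from a GTF file
#'
#' Inverse of [write_gtf()] for the exon features: returns the 0-based
#' half-open exon table the catalog builder consumes. Any GTF with gene_id
#' and transcript_id attributes on its exon lines will do.
#'
#' @param file GTF path.
#' @return data frame: gene_id, transcript_id, chrom, strand, start, end.
#' @export
read_gtf_exons <- function(file) {
  ln <- readLines(file)
  ln <- ln[!startsWith(ln, "#")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) == 9L]
  feat <- vapply(f, `[[`, "", 3L)
  f <- f[feat == "exon"]
  attr_field <- vapply(f, `[[`, "", 9L)
  grab <- function(key) {
    m <- regmatches(attr_field, regexec(paste0(key, ' "([^"]+)"'), attr_field))
    vapply(m, `[[`, "", 2L)
  }
  data.frame(gene_id = grab("gene_id"), transcript_id = grab("transcript_id"),
             chrom = vapply(f, `[[`, "", 1L),
             strand = vapply(f, `[[`, "", 7L),
             start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
             end = as.integer(vapply(f, `[[`, "", 5L)))
}

#' Write a coverage track as bedGraph
#' @param coverage data frame chrom, start, end, value.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bedgraph <- function(coverage, file) {
  lines <- sprintf("%s\t%d\t%d\t%s", coverage$chrom, coverage$start,
                   coverage$end, format(coverage$value, trim = TRUE,
                                        scientific = FALSE))
  writeLines(lines, file)
  invisible(file)
}

#' Read a bedGraph coverage track
#' @param file path.
#' @return data frame chrom, start, end, value.
#' @export
read_bedgraph <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "value")
  df
}

#' Write every artifact of a simulated study to a directory
#'
#' One-call emission of the synthetic study: genome FASTA, gene-model GTF,
#' event catalog, branchpoint table, per-condition junction/boundary counts,
#' qPCR Ct matrix and dilution series, and a coverage track. Running it twice
#' with the same configuration produces byte-identical files.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim_annotation(config)
  p <- c(genome = file.path(outdir, "genome.fa"),
         gtf = file.path(outdir, "genes.gtf"),
         events = file.path(outdir, "events.tsv"),
         branchpoints = file.path(outdir, "branchpoints.tsv"),
         junctions = file.path(outdir, "junction_counts.tsv"),
         boundaries = file.path(outdir, "boundary_counts.tsv"),
         ct = file.path(outdir, "qpcr_ct.tsv"),
         dilutions = file.path(outdir, "qpcr_dilutions.tsv"),
         coverage = file.path(outdir, "coverage.bedgraph"))
  write_genome_fasta(ann$genome, p["genome"])
  write_gtf(ann, p["gtf"])
  write_tsv_plain(ann$events, p["events"])
  write_tsv_plain(ann$branchpoints, p["branchpoints"])
  counts <- simulate_condition_counts(ann$events, config$true_psi,
                                      config$read_depth,
                                      seed = child_seed(config$seed, 2L))
  write_tsv_plain(counts$junctions, p["junctions"])
  write_tsv_plain(counts$boundaries, p["boundaries"])
  qp <- simulate_qpcr_panel(samples = c("control", "KD"),
                            assays = config$qpcr$assays,
                            alpha = config$qpcr$alpha,
                            noise_sd = config$qpcr$noise_sd,
                            n_replicates = config$qpcr$n_replicates,
                            seed = child_seed(config$seed, 3L))
  write_tsv_plain(qp$ct, p["ct"])
  write_tsv_plain(qp$dilutions, p["dilutions"])
  cov <- simulate_coverage_tracks(ann, seed = child_seed(config$seed, 4L))
  write_bedgraph(cov, p["coverage"])
  invisible(p)
}
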