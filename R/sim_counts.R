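#' Simulate junction and boundary read counts for one condition
#'
#' For each event the number of informative reads is drawn as
#' n ~ Poisson(depth) and split into inclusion reads I ~ Binomial(n, psi_true)
#' and exclusion reads E = n - I. Counts are then distributed onto the event's
#' physical junctions and exon-intron boundaries: both inclusion junctions of a
#' cassette exon (or both boundaries of a retained intron) receive I, the
#' skip (or spliced) junction receives E; competing-splice-site events place I
#' on the extension-isoform junction.
#'
#' @param events event catalog data frame (see [sim_annotation()] /
#'   [build_event_catalog()]).
#' @param true_psi per-event true inclusion level, recycled if length 1.
#' @param depth mean informative reads per event (Poisson); depth 0 yields
#'   empty count tables.
#' @param seed integer seed.
#' @return list with `junctions` (chrom, donor, acceptor, strand, count),
#'   `boundaries` (chrom, boundary_pos, side, strand, count) and `truth`
#'   (event_id, psi_true, n, I, E).
#' @export
simulate_condition_counts <- function(events, true_psi, depth, seed = 1L) {
  if (depth < 0) stopf("depth must be >= 0")
  if (nrow(events) > 0 &&
      (any(!nzchar(events$inclusion_keys)) || any(!nzchar(events$exclusion_keys)))) {
    stopf("event catalog contains events without junction definitions")
  }
  psi <- rep_len(true_psi, nrow(events))
  if (any(psi < 0 | psi > 1)) stopf("true_psi must lie in [0, 1]")
  with_seed(seed, {
    n <- if (depth == 0) integer(nrow(events)) else stats::rpois(nrow(events), depth)
    I <- stats::rbinom(nrow(events), n, psi)
    E <- n - I
    counts_to_tables(events, I, E, data.frame(
      event_id = events$event_id, psi_true = psi, n = n, I = I, E = E))
  })
}

# Distribute per-event inclusion/exclusion read totals onto physical keys and
# aggregate into the junction-count and boundary-count table formats.
counts_to_tables <- function(events, I, E, truth = NULL) {
  inc <- split_keys(events$inclusion_keys)
  exc <- split_keys(events$exclusion_keys)
  keys <- c(unlist(mapply(function(k, x) stats::setNames(rep(x, length(k)), k),
                          inc, I, SIMPLIFY = FALSE)),
            unlist(mapply(function(k, x) stats::setNames(rep(x, length(k)), k),
                          exc, E, SIMPLIFY = FALSE)))
  if (length(keys) == 0) {
    return(list(junctions = empty_junction_table(),
                boundaries = empty_boundary_table(), truth = truth))
  }
  agg <- tapply(keys, names(keys), sum)
  agg <- agg[agg > 0]                      # sparse tables: no zero-count rows
  if (length(agg) == 0) {
    return(list(junctions = empty_junction_table(),
                boundaries = empty_boundary_table(), truth = truth))
  }
  parts <- strsplit(names(agg), ":", fixed = TRUE)
  nf <- lengths(parts)
  is_bnd <- nf == 4L                       # chrom:pos:side:strand
  jt <- empty_junction_table(); bt <- empty_boundary_table()
  if (any(!is_bnd)) {
    p <- parts[!is_bnd]
    da <- strsplit(vapply(p, `[[`, "", 2L), "-", fixed = TRUE)
    jt <- data.frame(chrom = vapply(p, `[[`, "", 1L),
                     donor = as.integer(vapply(da, `[[`, "", 1L)),
                     acceptor = as.integer(vapply(da, `[[`, "", 2L)),
                     strand = vapply(p, `[[`, "", 3L),
                     count = as.vector(agg[!is_bnd]))
    jt <- jt[order(jt$chrom, jt$donor, jt$acceptor, jt$strand), , drop = FALSE]
    rownames(jt) <- NULL
  }
  if (any(is_bnd)) {
    p <- parts[is_bnd]
    bt <- data.frame(chrom = vapply(p, `[[`, "", 1L),
                     boundary_pos = as.integer(vapply(p, `[[`, "", 2L)),
                     side = vapply(p, `[[`, "", 3L),
                     strand = vapply(p, `[[`, "", 4L),
                     count = as.vector(agg[is_bnd]))
    bt <- bt[order(bt$chrom, bt$boundary_pos, bt$side), , drop = FALSE]
    rownames(bt) <- NULL
  }
  list(junctions = jt, boundaries = bt, truth = truth)
}

empty_junction_table <- function() {
  data.frame(chrom = character(), donor = integer(), acceptor = integer(),
             strand = character(), count = integer())
}
empty_boundary_table <- function() {
  data.frame(chrom = character(), boundary_pos = integer(), side = character(),
             strand = character(), count = integer())
}

#' True inclusion trajectory and counts along an ASO dose series
#'
#' The true delta-psi at dose d is `max_effect * d / max(doses)` for the
#' linear shape, and `max_effect * min(1, d / (2 * half_max))` for the
#' saturating shape — a ramp reaching the full effect at twice the half-max
#' dose, so saturation occurs before the top dose whenever
#' `2 * half_max < max(doses)`. Both shapes are monotone in dose by
#' construction.
#'
#' @param psi_base true inclusion at dose 0.
#' @param doses ascending doses (pmol).
#' @param max_effect signed maximal delta-psi.
#' @param shape "linear" or "saturating".
#' @param half_max dose at which the saturating shape reaches half the effect.
#' @param depth mean informative reads per dose point; 0 skips count sampling.
#' @param seed integer seed.
#' @return data frame with dose, psi_true, and (if depth > 0) n, I, E.
#' @export
simulate_dose_response <- function(psi_base, doses, max_effect,
                                   shape = c("linear", "saturating"),
                                   half_max = 50, depth = 0, seed = 1L) {
  shape <- match.arg(shape)
  if (is.unsorted(doses, strictly = TRUE)) stopf("doses must be sorted ascending")
  frac <- switch(shape,
                 linear = doses / max(doses),
                 saturating = pmin(1, doses / (2 * half_max)))
  psi <- pmin(1, pmax(0, psi_base + max_effect * frac))
  out <- data.frame(dose = doses, psi_true = psi)
  if (depth > 0) {
    with_seed(seed, {
      out$n <- stats::rpois(length(doses), depth)
      out$I <- stats::rbinom(length(doses), out$n, out$psi_true)
      out$E <- out$n - out$I
    })
  }
  out
}

#' Emit minimal SAM text for simulated junction/boundary counts
#'
#' Writes single-end 67-nt alignment records whose CIGAR block structure is
#' consistent with the supported junction (M/N/M) or boundary (single M block
#' centered on the boundary). Sequence and quality fields are placeholders;
#' the records carry exactly the information junction counting consumes.
#'
#' @param counts list as returned by [simulate_condition_counts()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param file path of the SAM text file to write.
#' @param read_len read length in nt.
#' @return `file`, invisibly.
#' @export
write_sam <- function(counts, chrom_sizes, file, read_len = 67L) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), chrom_sizes))
  recs <- character(0)
  j <- counts$junctions
  if (nrow(j) > 0) {
    left <- read_len %/% 2L
    right <- read_len - left
    for (i in seq_len(nrow(j))) {
      if (j$count[i] == 0) next
      pos1 <- j$donor[i] - left + 1L            # 1-based leftmost
      cigar <- sprintf("%dM%dN%dM", left, j$acceptor[i] - j$donor[i], right)
      flag <- if (j$strand[i] == "+") 0L else 16L
      recs <- c(recs, sprintf("jr%d.%d\t%d\t%s\t%d\t50\t%s\t*\t0\t0\t*\t*",
                              i, seq_len(j$count[i]), flag, j$chrom[i], pos1, cigar))
    }
  }
  b <- counts$boundaries
  if (nrow(b) > 0) {
    left <- read_len %/% 2L
    for (i in seq_len(nrow(b))) {
      if (b$count[i] == 0) next
      pos1 <- b$boundary_pos[i] - left + 1L
      flag <- if (b$strand[i] == "+") 0L else 16L
      recs <- c(recs, sprintf("br%d.%d\t%d\t%s\t%d\t50\t%dM\t*\t0\t0\t*\t*",
                              i, seq_len(b$count[i]), flag, b$chrom[i], pos1, read_len))
    }
  }
  writeLines(c(hdr, recs), file)
  invisible(file)
}
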