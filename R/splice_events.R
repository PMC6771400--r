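#' Derive the splicing-event catalog from gene models
#'
#' Compares transcript structures within each gene to enumerate cassette exons
#' (SE), retained introns (RI) and competing 5'/3' splice sites (A5SS/A3SS),
#' plus constitutive junctions (adjacent splice junctions never alternative in
#' any transcript) and the cross-product of annotated donors x acceptors as
#' candidate novel junctions.
#'
#' Detection rules, on the set of junctions (intron left/right coordinates)
#' and exons per transcript:
#' \itemize{
#'   \item SE: a skip junction (l, r) coexists with an exon (m1, m2) flanked
#'     by junctions (l, m1) and (m2, r).
#'   \item RI: a junction (l, r) coexists with an exon covering the whole
#'     intron.
#'   \item A5SS/A3SS: two junctions share one genomic end; which splice site
#'     varies (donor vs acceptor) depends on strand. Psi is oriented so that
#'     inclusion means the extension-containing (long-exon) isoform.
#' }
#'
#' @param exons data frame with gene_id, transcript_id, chrom, strand, start,
#'   end (0-based half-open).
#' @return list with `events` (catalog data frame), `novel_junctions`
#'   (candidate donor x acceptor keys per gene).
#' @export
build_event_catalog <- function(exons) {
  ev <- list(); novel <- list()
  for (gid in unique(exons$gene_id)) {
    gx <- exons[exons$gene_id == gid, , drop = FALSE]
    strand <- unique(gx$strand)
    if (length(strand) != 1) stopf("gene %s has transcripts on mixed strands", gid)
    chrom <- gx$chrom[1]
    txs <- split(gx[order(gx$start), ], gx$transcript_id[order(gx$start)])
    juncs_by_tx <- lapply(txs, function(t) {
      if (nrow(t) < 2) return(cbind(l = integer(0), r = integer(0)))
      cbind(l = t$end[-nrow(t)], r = t$start[-1])
    })
    jall <- unique(do.call(rbind, juncs_by_tx))
    jset <- paste(jall[, 1], jall[, 2])
    exall <- unique(gx[, c("start", "end")])

    rows <- list()
    used <- character(0)
    # cassette exons
    for (i in seq_len(nrow(jall))) {
      l <- jall[i, 1]; r <- jall[i, 2]
      mids <- exall[exall$start > l & exall$end < r, , drop = FALSE]
      for (m in seq_len(nrow(mids))) {
        k_in1 <- paste(l, mids$start[m]); k_in2 <- paste(mids$end[m], r)
        if (k_in1 %in% jset && k_in2 %in% jset) {
          inc <- c(junction_key(chrom, l, mids$start[m], strand),
                   junction_key(chrom, mids$end[m], r, strand))
          exc <- junction_key(chrom, l, r, strand)
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = sprintf("%s.SE.%d-%d", gid, mids$start[m], mids$end[m]),
            kind = "SE", gene_id = gid, chrom = chrom, strand = strand,
            region_start = mids$start[m], region_end = mids$end[m],
            inclusion_keys = paste(inc, collapse = ";"), exclusion_keys = exc)
          used <- c(used, paste(l, r), k_in1, k_in2)
        }
      }
    }
    # retained introns
    for (i in seq_len(nrow(jall))) {
      l <- jall[i, 1]; r <- jall[i, 2]
      if (any(exall$start < l & exall$end > r)) {
        side5 <- if (strand == "+") "5p" else "3p"
        side3 <- if (strand == "+") "3p" else "5p"
        inc <- c(boundary_key(chrom, l, side5, strand),
                 boundary_key(chrom, r, side3, strand))
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = sprintf("%s.RI.%d-%d", gid, l, r),
          kind = "RI", gene_id = gid, chrom = chrom, strand = strand,
          region_start = l, region_end = r,
          inclusion_keys = paste(inc, collapse = ";"),
          exclusion_keys = junction_key(chrom, l, r, strand))
        used <- c(used, paste(l, r))
      }
    }
    # competing splice sites: junction pairs sharing one genomic end
    if (nrow(jall) >= 2) {
      for (l in unique(jall[, 1])) {
        rs <- sort(jall[jall[, 1] == l, 2])
        if (length(rs) < 2) next
        for (a in seq_len(length(rs) - 1L)) for (b in seq((a + 1L), length(rs))) {
          r1 <- rs[a]; r2 <- rs[b]
          # skip SE-shaped pairs: an exon starts at r1 and rejoins at r2
          se_like <- any(vapply(seq_len(nrow(exall)), function(e) {
            exall$start[e] == r1 && paste(exall$end[e], r2) %in% jset
          }, logical(1)))
          if (se_like) next
          kind <- if (strand == "+") "A3SS" else "A5SS"
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = sprintf("%s.%s.%d-%d", gid, kind, r1, r2),
            kind = kind, gene_id = gid, chrom = chrom, strand = strand,
            region_start = r1, region_end = r2,
            inclusion_keys = junction_key(chrom, l, r1, strand),
            exclusion_keys = junction_key(chrom, l, r2, strand))
          used <- c(used, paste(l, r1), paste(l, r2))
        }
      }
      for (r in unique(jall[, 2])) {
        ls <- sort(jall[jall[, 2] == r, 1])
        if (length(ls) < 2) next
        for (a in seq_len(length(ls) - 1L)) for (b in seq((a + 1L), length(ls))) {
          l1 <- ls[a]; l2 <- ls[b]
          se_like <- any(vapply(seq_len(nrow(exall)), function(e) {
            exall$end[e] == l2 && paste(l1, exall$start[e]) %in% jset
          }, logical(1)))
          if (se_like) next
          kind <- if (strand == "+") "A5SS" else "A3SS"
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = sprintf("%s.%s.%d-%d", gid, kind, l1, l2),
            kind = kind, gene_id = gid, chrom = chrom, strand = strand,
            region_start = l1, region_end = l2,
            inclusion_keys = junction_key(chrom, l2, r, strand),
            exclusion_keys = junction_key(chrom, l1, r, strand))
          used <- c(used, paste(l1, r), paste(l2, r))
        }
      }
    }
    # constitutive junctions: shared by every transcript, untouched by events
    multi <- juncs_by_tx[vapply(juncs_by_tx, nrow, 0L) >= 0]
    if (length(txs) >= 1 && nrow(jall) > 0) {
      in_all <- vapply(seq_len(nrow(jall)), function(i) {
        all(vapply(juncs_by_tx, function(j) {
          any(j[, 1] == jall[i, 1] & j[, 2] == jall[i, 2])
        }, logical(1)))
      }, logical(1))
      const <- jall[in_all & !(jset %in% used), , drop = FALSE]
      for (i in seq_len(nrow(const))) {
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = sprintf("%s.CJ.%d-%d", gid, const[i, 1], const[i, 2]),
          kind = "CONST_JUNCTION", gene_id = gid, chrom = chrom, strand = strand,
          region_start = const[i, 1], region_end = const[i, 2],
          inclusion_keys = junction_key(chrom, const[i, 1], const[i, 2], strand),
          exclusion_keys = "")
      }
    }
    ev[[gid]] <- if (length(rows)) do.call(rbind, rows) else NULL
    # candidate novel junctions: annotated donors x acceptors (strand-aware)
    donors <- if (strand == "+") unique(jall[, 1]) else unique(jall[, 2])
    acceptors <- if (strand == "+") unique(jall[, 2]) else unique(jall[, 1])
    if (length(donors) && length(acceptors)) {
      grid <- expand.grid(donor = donors, acceptor = acceptors)
      novel[[gid]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                                 donor = grid$donor, acceptor = grid$acceptor)
    }
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    events <- data.frame(event_id = character(), kind = character(),
                         gene_id = character(), chrom = character(),
                         strand = character(), region_start = integer(),
                         region_end = integer(), inclusion_keys = character(),
                         exclusion_keys = character())
  }
  rownames(events) <- NULL
  list(events = events, novel_junctions = do.call(rbind, novel))
}

#' Count junction-spanning and boundary-spanning reads
#'
#' SAM-text mode: each alignment record contributes to a junction when a gap
#' in its block structure matches the junction coordinates exactly and both
#' flanking aligned blocks are at least `min_overhang` nt; it contributes to a
#' retained-intron boundary when a single aligned block covers at least
#' `min_overhang` nt on each side of the boundary. Records flagged
#' non-primary/supplementary or with mapping quality 0 are dropped; the
#' protocol is strand-specific, so only records on the catalog strand count.
#' One read supports a given junction or boundary at most once. Malformed
#' records are skipped and tallied.
#'
#' TSV mode: junction/boundary count tables pass through unchanged.
#'
#' @param alignments path to a SAM text file (or character vector of SAM
#'   lines), or a list with precomputed `junctions`/`boundaries` tables.
#' @param catalog event catalog; supplies the boundary positions of interest.
#' @param min_overhang minimum anchor length on each side, nt.
#' @return list with `junctions`, `boundaries` count tables and `n_skipped`.
#' @export
count_junction_reads <- function(alignments, catalog, min_overhang = 6L) {
  if (is.list(alignments) && !is.null(alignments$junctions)) {
    return(list(junctions = alignments$junctions,
                boundaries = alignments$boundaries %||% empty_boundary_table(),
                n_skipped = 0L))
  }
  lines <- if (length(alignments) == 1L && file.exists(alignments)) {
    readLines(alignments)
  } else as.character(alignments)
  lines <- lines[!startsWith(lines, "@")]
  n_skipped <- 0L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 11L
  n_skipped <- n_skipped + sum(!ok)
  fields <- fields[ok]
  if (length(fields) == 0) {
    return(list(junctions = empty_junction_table(),
                boundaries = empty_boundary_table(), n_skipped = n_skipped))
  }
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  chrom <- vapply(fields, `[[`, "", 3L)
  cigar <- vapply(fields, `[[`, "", 6L)
  bad <- is.na(flag) | is.na(pos) | is.na(mapq) |
    !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  n_skipped <- n_skipped + sum(bad)
  keep <- !bad & bitwAnd(flag, 0x900) == 0L & mapq > 0L
  flag <- flag[keep]; pos <- pos[keep]; chrom <- chrom[keep]; cigar <- cigar[keep]
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")

  jt <- empty_junction_table(); bt <- empty_boundary_table()
  if (length(cigar)) {
    blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, pos = pos, ops = c("M", "=", "X"), reduce.ranges = TRUE)
    jkeys <- character(0)
    bnd <- catalog_boundaries(catalog)
    bhits <- character(0)
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      s0 <- BiocGenerics::start(b) - 1L   # 0-based starts
      e0 <- BiocGenerics::end(b)          # 0-based half-open ends
      w <- e0 - s0
      nb <- length(s0)
      if (nb >= 2) {
        for (k in seq_len(nb - 1L)) {
          if (w[k] >= min_overhang && w[k + 1L] >= min_overhang) {
            jkeys <- c(jkeys, junction_key(chrom[i], e0[k], s0[k + 1L], strand[i]))
          }
        }
      }
      if (nrow(bnd)) {
        hit <- bnd$chrom == chrom[i] & bnd$strand == strand[i] &
          vapply(seq_len(nrow(bnd)), function(j) {
            any(s0 <= bnd$boundary_pos[j] - min_overhang &
                  e0 >= bnd$boundary_pos[j] + min_overhang)
          }, logical(1))
        bhits <- c(bhits, boundary_key(bnd$chrom[hit], bnd$boundary_pos[hit],
                                       bnd$side[hit], bnd$strand[hit]))
      }
    }
    if (length(jkeys)) {
      tab <- table(jkeys)
      parts <- strsplit(names(tab), ":", fixed = TRUE)
      da <- strsplit(vapply(parts, `[[`, "", 2L), "-", fixed = TRUE)
      jt <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                       donor = as.integer(vapply(da, `[[`, "", 1L)),
                       acceptor = as.integer(vapply(da, `[[`, "", 2L)),
                       strand = vapply(parts, `[[`, "", 3L),
                       count = as.integer(tab))
      jt <- jt[order(jt$chrom, jt$donor, jt$acceptor), , drop = FALSE]
      rownames(jt) <- NULL
    }
    if (length(bhits)) {
      tab <- table(bhits)
      parts <- strsplit(names(tab), ":", fixed = TRUE)
      bt <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                       boundary_pos = as.integer(vapply(parts, `[[`, "", 2L)),
                       side = vapply(parts, `[[`, "", 3L),
                       strand = vapply(parts, `[[`, "", 4L),
                       count = as.integer(tab))
      bt <- bt[order(bt$chrom, bt$boundary_pos, bt$side), , drop = FALSE]
      rownames(bt) <- NULL
    }
  }
  list(junctions = jt, boundaries = bt, n_skipped = n_skipped)
}

# Boundary positions of interest from an event catalog (RI inclusion keys).
catalog_boundaries <- function(catalog) {
  keys <- unlist(split_keys(catalog$inclusion_keys[catalog$kind == "RI"]))
  if (!length(keys)) return(empty_boundary_table())
  parts <- strsplit(unique(keys), ":", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[[`, "", 1L),
             boundary_pos = as.integer(vapply(parts, `[[`, "", 2L)),
             side = vapply(parts, `[[`, "", 3L),
             strand = vapply(parts, `[[`, "", 4L),
             count = 0L)
}

#' Estimate percent spliced in (PSI) for every cataloged event
#'
#' Inclusion support I and exclusion support E per event kind:
#' \itemize{
#'   \item SE: I = mean (or sum, see `average`) of the two inclusion-junction
#'     counts; E = skip-junction count.
#'   \item RI: I = mean of the 5' and 3' exon-intron boundary counts
#'     (retention support); E = spliced-junction count.
#'   \item A5SS/A3SS: I = extension-isoform junction count; E = short-isoform
#'     junction count.
#'   \item CONST_JUNCTION: I = annotated-junction count; E = all other reads
#'     on junctions sharing either splice site.
#' }
#' Psi = I / (I + E); undefined (NA) when no informative reads. Events are
#' reportable as alternatively spliced only when n = I + E >= 20.
#'
#' @param counts list with `junctions` and `boundaries` count tables.
#' @param events event catalog.
#' @param sample sample identifier recorded in the output.
#' @param average `"mean"` (default) or `"sum"` aggregation of the paired
#'   inclusion supports of SE/RI events.
#' @return data frame: event_id, kind, sample, I, E, n, psi.
#' @export
estimate_psi <- function(counts, events, sample = "sample", average = c("mean", "sum")) {
  average <- match.arg(average)
  jt <- counts$junctions; bt <- counts$boundaries %||% empty_boundary_table()
  jmap <- stats::setNames(jt$count, junction_key(jt$chrom, jt$donor, jt$acceptor, jt$strand))
  bmap <- stats::setNames(bt$count, boundary_key(bt$chrom, bt$boundary_pos, bt$side, bt$strand))
  lookup <- function(keys) {
    is_bnd <- lengths(strsplit(keys, ":", fixed = TRUE)) == 4L
    v <- ifelse(is_bnd, bmap[keys], jmap[keys])
    v[is.na(v)] <- 0
    unname(v)
  }
  agg <- if (average == "mean") mean else sum
  inc <- split_keys(events$inclusion_keys)
  I <- vapply(inc, function(k) agg(lookup(k)), numeric(1))
  E <- numeric(nrow(events))
  has_exc <- nzchar(events$exclusion_keys)
  E[has_exc] <- vapply(split_keys(events$exclusion_keys[has_exc]),
                       function(k) agg(lookup(k)), numeric(1))
  cj <- events$kind == "CONST_JUNCTION"
  if (any(cj)) {
    for (i in which(cj)) {
      share <- jt$chrom == events$chrom[i] & jt$strand == events$strand[i] &
        (jt$donor == events$region_start[i] | jt$acceptor == events$region_end[i])
      E[i] <- sum(jt$count[share]) - I[i]
    }
  }
  n <- I + E
  data.frame(event_id = events$event_id, kind = events$kind, sample = sample,
             I = I, E = E, n = n, psi = ifelse(n > 0, I / n, NA_real_))
}

#' Pearson concordance between two PSI estimators
#'
#' @param psi_a,psi_b PSI tables from [estimate_psi()] (or any table with
#'   event_id and psi columns).
#' @return list with r (Pearson correlation over events with defined psi in
#'   both tables) and n_shared; r is NA with a warning below 3 shared events.
#' @export
estimator_concordance <- function(psi_a, psi_b) {
  m <- merge(psi_a[, c("event_id", "psi")], psi_b[, c("event_id", "psi")],
             by = "event_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) {
    warnf("fewer than 3 shared events with defined psi; concordance undefined")
    return(list(r = NA_real_, n_shared = nrow(m)))
  }
  list(r = stats::cor(m$psi.x, m$psi.y), n_shared = nrow(m))
}
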