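#' Centromere annotation and TIP landscape statistics
#'
#' Transposon insertion polymorphisms (TIPs) called across a panel of
#' accessions are classified by chromosome compartment (centromere /
#' pericentromere / arm) and genic context, after support-read filtering.
#' Centromeres are called from the density of centromere-specific repeat
#' hits: hits above a similarity cutoff are counted in fixed windows, and
#' runs of windows exceeding a hit threshold form the centromere; the
#' pericentromere is annotated as 10% of the chromosome length split on
#' both sides of it.
#'
#' All coordinates are BED-style 0-based half-open `[start, end)`.
#'
#' @name tip-landscape
NULL

#' Call centromeres and compartmentalise chromosomes from repeat-hit density
#'
#' @param hits data.frame with columns `chrom`, `start`, `end`,
#'   `similarity` (percent) — typically BLAST-style hits of a
#'   centromere-specific repeat against the genome.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window Window size in bp, default 100000.
#' @param min_hits A window is centromeric when its hit count is strictly
#'   greater than this, default 6.
#' @param min_similarity Hits at similarity strictly greater than this are
#'   counted, default 70.
#' @param largest_only Keep only the longest run of flagged windows per
#'   chromosome, default `FALSE` (all runs kept as centromeric).
#' @param peri_fraction Total pericentromere length as a fraction of the
#'   chromosome, default 0.10, split equally on both sides and truncated
#'   at chromosome ends.
#' @details Hits are assigned to windows by their midpoint.  A chromosome
#'   with no flagged window gets no centromere (whole chromosome = arm)
#'   and a warning.
#' @return A `centromere_annotation`: data.frame `chrom`, `start`, `end`,
#'   `compartment` in `{centromere, pericentromere, arm}` whose intervals
#'   are disjoint and tile each chromosome exactly; parameters kept as
#'   attributes.
#' @export
call_centromeres <- function(hits, chrom_lengths, window = 100000,
                             min_hits = 6, min_similarity = 70,
                             largest_only = FALSE, peri_fraction = 0.10) {
  stopifnot(all(c("chrom", "start", "end", "similarity") %in% names(hits)))
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named", call. = FALSE)
  hits <- hits[hits$similarity > min_similarity, , drop = FALSE]
  bad <- setdiff(unique(hits$chrom), names(chrom_lengths))
  if (length(bad))
    stop("hits on unknown chromosome(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  rows <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    h <- hits[hits$chrom == chrom, , drop = FALSE]
    mid <- floor((h$start + h$end) / 2)
    win <- floor(mid / window)                 # 0-based window index
    n_win <- ceiling(L / window)
    counts <- tabulate(win + 1L, nbins = n_win)
    flagged <- which(counts > min_hits)        # strict: "more than"
    if (length(flagged) == 0L) {
      warning("no centromere called on ", chrom,
              "; whole chromosome labelled arm", call. = FALSE)
      rows[[chrom]] <- data.frame(chrom = chrom, start = 0, end = L,
                                  compartment = "arm",
                                  stringsAsFactors = FALSE)
      next
    }
    runs <- IRanges::reduce(IRanges::IRanges(start = flagged,
                                             width = 1L))
    if (largest_only)
      runs <- runs[which.max(IRanges::width(runs))]
    cen <- data.frame(
      start = (BiocGenerics::start(runs) - 1L) * window,
      end = pmin(BiocGenerics::end(runs) * window, L)
    )
    rows[[chrom]] <- cbind(chrom = chrom,
                           .compartment_segments(L, cen, peri_fraction),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("centromere_annotation", "data.frame"),
            window = window, min_hits = min_hits,
            min_similarity = min_similarity,
            peri_fraction = peri_fraction,
            chrom_lengths = chrom_lengths)
}

# Tile one chromosome into arm / pericentromere / centromere segments
# around the centromere interval(s) in `cen` (columns start, end, sorted).
# Pericentromere = peri_fraction/2 * L on each outer side, truncated at
# chromosome ends; gaps between multiple centromere runs stay arm.
.compartment_segments <- function(L, cen, peri_fraction = 0.10) {
  flank <- peri_fraction / 2 * L
  peri_l <- c(max(0, cen$start[1] - flank), cen$start[1])
  peri_r <- c(cen$end[nrow(cen)], min(L, cen$end[nrow(cen)] + flank))
  seg <- rbind(
    if (peri_l[1] > 0)
      data.frame(start = 0, end = peri_l[1], compartment = "arm"),
    if (peri_l[2] > peri_l[1])
      data.frame(start = peri_l[1], end = peri_l[2],
                 compartment = "pericentromere"),
    do.call(rbind, lapply(seq_len(nrow(cen)), function(i) {
      gap <- if (i < nrow(cen))
        data.frame(start = cen$end[i], end = cen$start[i + 1],
                   compartment = "arm")
      rbind(data.frame(start = cen$start[i], end = cen$end[i],
                       compartment = "centromere"), gap)
    })),
    if (peri_r[2] > peri_r[1])
      data.frame(start = peri_r[1], end = peri_r[2],
                 compartment = "pericentromere"),
    if (peri_r[2] < L)
      data.frame(start = peri_r[2], end = L, compartment = "arm")
  )
  seg
}

#' Compartment annotation from known centromere intervals
#'
#' Builds the same `centromere_annotation` object as [call_centromeres()]
#' but from already-known centromere coordinates — used to turn the
#' synthetic generator's truth table into an annotation, or to import an
#' external centromere call.
#'
#' @param centromeres data.frame `chrom`, `start`, `end` (0-based
#'   half-open centromere intervals; several rows per chromosome
#'   allowed).
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param peri_fraction Total pericentromere fraction, default 0.10.
#' @return A `centromere_annotation` tiling each chromosome.
#' @export
compartments_from_truth <- function(centromeres, chrom_lengths,
                                    peri_fraction = 0.10) {
  stopifnot(all(c("chrom", "start", "end") %in% names(centromeres)))
  rows <- lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    cen <- centromeres[centromeres$chrom == chrom, , drop = FALSE]
    if (nrow(cen) == 0L)
      return(data.frame(chrom = chrom, start = 0, end = L,
                        compartment = "arm", stringsAsFactors = FALSE))
    cen <- cen[order(cen$start), , drop = FALSE]
    cbind(chrom = chrom, .compartment_segments(L, cen, peri_fraction),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("centromere_annotation", "data.frame"),
            peri_fraction = peri_fraction, chrom_lengths = chrom_lengths)
}

#' Classify positions by chromosome compartment
#'
#' Point-in-interval lookup against a [call_centromeres()] annotation;
#' intervals are half-open `[start, end)`.
#'
#' @param chrom,position Vectors of chromosome names and 0-based
#'   positions.
#' @param ann A `centromere_annotation`.
#' @return Character vector of compartment labels.
#' @export
classify_compartment <- function(chrom, position, ann) {
  stopifnot(inherits(ann, "centromere_annotation"))
  vapply(seq_along(chrom), function(i) {
    seg <- ann[ann$chrom == chrom[i], , drop = FALSE]
    if (nrow(seg) == 0L)
      stop("chromosome not annotated: ", chrom[i], call. = FALSE)
    hit <- seg$start <= position[i] & position[i] < seg$end
    if (!any(hit))
      stop("position ", position[i], " outside ", chrom[i], call. = FALSE)
    seg$compartment[which(hit)[1L]]
  }, character(1))
}

#' Classify positions as genic or intergenic
#'
#' A position is genic when it lies within a gene body (full annotated
#' span, introns and UTRs included) extended by `flank` bp on both sides.
#'
#' @param chrom,position Vectors of chromosome names and 0-based
#'   positions.
#' @param genes data.frame `chrom`, `start`, `end` (0-based half-open) or
#'   a `GRanges`.
#' @param flank Flank size in bp, default 2000.
#' @return Character vector, `"genic"` or `"intergenic"`.
#' @export
classify_genic <- function(chrom, position, genes, flank = 2000) {
  if (methods::is(genes, "GRanges")) {
    genes <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = BiocGenerics::start(genes) - 1L,
      end = BiocGenerics::end(genes),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(genes)))
  levs <- union(unique(as.character(chrom)),
                unique(as.character(genes$chrom)))
  gr_genes <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = levs),
    IRanges::IRanges(start = pmax(0, genes$start - flank) + 1L,
                     end = genes$end + flank)
  )
  gr_tips <- GenomicRanges::GRanges(
    factor(chrom, levels = levs),
    IRanges::IRanges(start = position + 1L, width = 1L))
  ov <- GenomicRanges::countOverlaps(gr_tips, gr_genes)
  ifelse(ov > 0, "genic", "intergenic")
}

#' Filter TIPs by supporting-read count
#'
#' Retains TIPs with strictly more than `min_support` supporting reads
#' (split or discordant), the filter applied before any landscape
#' statistic.
#'
#' @param tips data.frame with a `support_reads` column.
#' @param min_support Threshold, default 5 (i.e. keep support >= 6).
#' @return The retained rows.
#' @export
filter_tips <- function(tips, min_support = 5) {
  stopifnot("support_reads" %in% names(tips))
  out <- tips[tips$support_reads > min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.n_accessions <- function(tips) {
  if ("n_accessions" %in% names(tips)) return(tips$n_accessions)
  if (!"accessions" %in% names(tips))
    stop("tips need an 'accessions' (comma-joined) or 'n_accessions' column",
         call. = FALSE)
  lengths(strsplit(as.character(tips$accessions), ",", fixed = TRUE))
}

#' Sharing spectrum of TIPs across accessions
#'
#' @param tips data.frame with an `accessions` column (comma-joined ids)
#'   or an `n_accessions` count column.
#' @param n_accessions Total panel size; default the maximum observed.
#' @return List with `spectrum` (data.frame `n_accessions`, `n_tips`,
#'   `fraction` over 1..panel size) and `fraction_le2`, the fraction of
#'   TIPs present in one or two accessions.
#' @export
sharing_spectrum <- function(tips, n_accessions = NULL) {
  k <- .n_accessions(tips)
  if (length(k) == 0L) stop("no TIPs", call. = FALSE)
  if (is.null(n_accessions)) n_accessions <- max(k)
  counts <- tabulate(k, nbins = n_accessions)
  list(
    spectrum = data.frame(
      n_accessions = seq_len(n_accessions), n_tips = counts,
      fraction = counts / length(k)
    ),
    fraction_le2 = sum(k <= 2) / length(k)
  )
}

.p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 5e-2, "*", "ns"))))
}

#' Per-group TIP burden across accessions, with pairwise Welch t-tests
#'
#' For each element group, counts the TIPs carried by each accession (a
#' TIP contributes to every accession in its accession set), then reports
#' mean +/- sample sd per group and two-sided Welch t-tests between all
#' group pairs, starred at the 0.05 / 0.01 / 0.001 / 0.0001 thresholds.
#'
#' @param tips data.frame with `group` and `accessions` (comma-joined)
#'   columns.
#' @param accessions Character vector of panel accession ids; default all
#'   ids observed.
#' @return List with `per_accession` (group x accession count matrix),
#'   `summary` (group, n_accessions, mean, sd) and `tests` (group_a,
#'   group_b, t, df, p_value, stars).
#' @export
group_summary <- function(tips, accessions = NULL) {
  stopifnot(all(c("group", "accessions") %in% names(tips)))
  acc_list <- strsplit(as.character(tips$accessions), ",", fixed = TRUE)
  if (is.null(accessions)) accessions <- sort(unique(unlist(acc_list)))
  if (length(accessions) < 2L)
    stop("need at least two accessions", call. = FALSE)
  groups <- sort(unique(as.character(tips$group)))
  mat <- matrix(0L, length(groups), length(accessions),
                dimnames = list(groups, accessions))
  for (i in seq_len(nrow(tips))) {
    g <- as.character(tips$group[i])
    hit <- intersect(acc_list[[i]], accessions)
    mat[g, hit] <- mat[g, hit] + 1L
  }
  summ <- data.frame(
    group = groups,
    n_accessions = length(accessions),
    mean = rowMeans(mat),
    sd = apply(mat, 1, stats::sd),
    stringsAsFactors = FALSE
  )
  tests <- NULL
  if (length(groups) >= 2L) {
    cmb <- utils::combn(groups, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      x <- mat[cmb[1, j], ]
      y <- mat[cmb[2, j], ]
      if (stats::sd(x) == 0 && stats::sd(y) == 0 &&
          mean(x) == mean(y)) {
        tt <- list(statistic = c(t = 0), parameter = c(df = NA),
                   p.value = 1)
      } else {
        tt <- stats::t.test(x, y, var.equal = FALSE)
      }
      data.frame(group_a = cmb[1, j], group_b = cmb[2, j],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, stars = .p_stars(tt$p.value),
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_accession = mat, summary = summ, tests = tests)
}

#' Annotate a filtered TIP table with compartment and genic labels
#'
#' @param tips data.frame with `chrom`, `position`, plus the columns used
#'   by the downstream statistics.
#' @param ann A `centromere_annotation`.
#' @param genes Gene intervals (see [classify_genic()]).
#' @param flank Genic flank in bp, default 2000.
#' @return `tips` with `compartment` and `genic` columns appended.
#' @export
annotate_tips <- function(tips, ann, genes, flank = 2000) {
  tips$compartment <- classify_compartment(tips$chrom, tips$position, ann)
  tips$genic <- classify_genic(tips$chrom, tips$position, genes, flank)
  tips
}
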