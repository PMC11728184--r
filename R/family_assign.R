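#' LTR family clustering, 80-80-80 assignment, and consensus
#'
#' Retrotransposon families are defined operationally: two sequences
#' belong to one family when they share at least 80% identity over at
#' least 80% of the query's length, and the query is at least 80 bp (the
#' 80-80-80 rule).  This module clusters LTR sequences into families with
#' deterministic greedy centroid clustering at an identity threshold,
#' assigns queries to a family database under the 80-80-80 rule, and
#' extracts majority-rule consensus sequences from alignments.
#'
#' @name family-assign
NULL

#' Assign a query sequence to a family under the 80-80-80 rule
#'
#' The query is globally aligned against every database sequence; the
#' best hit (highest identity, ties broken by longer aligned region then
#' lexicographic family id) is accepted only if identity >= `min_identity`,
#' coverage >= `min_coverage`, and the query is at least `min_length` bp.
#'
#' @param query A nucleotide sequence.
#' @param family_db Named sequences (names = family ids); a family may be
#'   represented by several sequences named `family|member`, in which
#'   case the part before the first `|` is the family id.
#' @param min_identity,min_coverage Percent thresholds, default 80.
#' @param min_length Minimum query length in bp, default 80.
#' @param ... Scoring parameters for [align_global()].
#' @return A one-row data.frame: `query_id`, `family_id` (or
#'   `"unassigned"`), `percent_identity`, `alignment_coverage`,
#'   `query_length`, `reason` (why unassigned, `NA` otherwise).
#' @export
assign_family <- function(query, family_db, min_identity = 80,
                          min_coverage = 80, min_length = 80, ...) {
  db <- .as_named_character(family_db)
  if (length(db) == 0L) stop("empty family database", call. = FALSE)
  q <- .as_named_character(query)
  query_id <- names(q)[1L]
  q <- q[[1L]]
  qlen <- nchar(q)

  unassigned <- function(reason, pid = NA_real_, cov = NA_real_) {
    data.frame(query_id = query_id, family_id = "unassigned",
               percent_identity = pid, alignment_coverage = cov,
               query_length = qlen, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (qlen < min_length) return(unassigned("query_too_short"))

  fam_of <- sub("\\|.*$", "", names(db))
  hits <- lapply(seq_along(db), function(i) {
    pr <- align_global(q, db[[i]], ...)
    pid <- percent_identity(pr, query = "a")
    data.frame(family_id = fam_of[i], identity = pid$identity,
               coverage = pid$coverage,
               aligned_columns = pid$aligned_columns,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$identity, -hits$aligned_columns,
                     hits$family_id), , drop = FALSE]
  best <- hits[1L, ]
  if (best$identity < min_identity)
    return(unassigned("identity_below_threshold", best$identity,
                      best$coverage))
  if (best$coverage < min_coverage)
    return(unassigned("coverage_below_threshold", best$identity,
                      best$coverage))
  data.frame(query_id = query_id, family_id = best$family_id,
             percent_identity = best$identity,
             alignment_coverage = best$coverage,
             query_length = qlen, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Greedy centroid clustering of LTR sequences
#'
#' Deterministic stand-in for a mean-shift sequence clusterer: sequences
#' are visited in order of decreasing length (ties by name); each joins
#' the first existing centroid to which its alignment identity reaches
#' the threshold, otherwise it founds a new cluster whose centroid it
#' becomes.
#'
#' @param seqs Named nucleotide sequences.
#' @param id_threshold Identity threshold as a fraction, default 0.80.
#' @param ... Scoring parameters for [align_global()].
#' @return data.frame `seq_id`, `cluster_id` (`fam_1`, `fam_2`, ... in
#'   founding order), `is_centroid`, `identity_to_centroid` (%); attribute
#'   `centroids` maps cluster id to centroid sequence id.
#' @export
cluster_ltrs <- function(seqs, id_threshold = 0.80, ...) {
  seqs <- .as_named_character(seqs)
  if (length(seqs) < 1L) stop("need at least one sequence", call. = FALSE)
  ord <- order(-nchar(seqs), names(seqs))
  centroids <- character(0)   # seq ids
  members <- data.frame(seq_id = character(0), cluster_id = character(0),
                        is_centroid = logical(0),
                        identity_to_centroid = numeric(0),
                        stringsAsFactors = FALSE)
  for (i in ord) {
    id <- names(seqs)[i]
    placed <- FALSE
    for (k in seq_along(centroids)) {
      pr <- align_global(seqs[[i]], seqs[[centroids[k]]], ...)
      pid <- percent_identity(pr, query = "a")
      if (pid$identity >= 100 * id_threshold) {
        members <- rbind(members, data.frame(
          seq_id = id, cluster_id = paste0("fam_", k),
          is_centroid = FALSE, identity_to_centroid = pid$identity,
          stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      members <- rbind(members, data.frame(
        seq_id = id, cluster_id = paste0("fam_", length(centroids)),
        is_centroid = TRUE, identity_to_centroid = 100,
        stringsAsFactors = FALSE))
    }
  }
  members <- members[match(names(seqs), members$seq_id), , drop = FALSE]
  rownames(members) <- NULL
  attr(members, "centroids") <-
    stats::setNames(centroids, paste0("fam_", seq_along(centroids)))
  attr(members, "id_threshold") <- id_threshold
  members
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent symbol is emitted if its fraction
#' reaches the threshold, otherwise the ambiguity symbol (`N` for
#' nucleotide alignments, `X` for protein).  Columns whose winner is the
#' gap character emit a gap, stripped from the ungapped consensus.
#'
#' @param alignment Named gapped sequences of equal length (e.g. from
#'   [align_star()]).
#' @param threshold Majority fraction, default 0.7.
#' @param alphabet `"auto"` (default), `"dna"` or `"protein"` — controls
#'   the ambiguity symbol.
#' @return A `consensus_profile` list: `alignment`, gapped `consensus`,
#'   `consensus_ungapped`, `per_column_support` (winning fraction per
#'   column) and `threshold`.
#' @export
consensus_profile <- function(alignment, threshold = 0.7,
                              alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  rows <- .as_named_character(alignment)
  if (length(rows) == 0L) stop("empty alignment", call. = FALSE)
  wid <- unique(nchar(rows))
  if (length(wid) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  if (alphabet == "auto") {
    alphabet <- if (grepl("^[ACGTN-]*$", paste(rows, collapse = "")))
      "dna" else "protein"
  }
  amb <- if (alphabet == "dna") "N" else "X"
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  cons <- character(wid)
  support <- numeric(wid)
  for (j in seq_len(wid)) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    # deterministic tie-break: alphabetical among equally frequent
    top <- sort(names(tab)[tab == tab[1L]])[1L]
    frac <- tab[[1L]] / nrow(m)
    support[j] <- frac
    cons[j] <- if (frac >= threshold) top else amb
  }
  structure(list(
    alignment = rows,
    consensus = paste(cons, collapse = ""),
    consensus_ungapped = paste(cons[cons != "-"], collapse = ""),
    per_column_support = support,
    threshold = threshold, alphabet = alphabet
  ), class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("<consensus_profile> ", length(x$alignment), " rows x ",
      nchar(x$consensus), " columns (", x$alphabet, ", threshold ",
      x$threshold, ")\n", sep = "")
  cat(" consensus: ",
      if (nchar(x$consensus_ungapped) > 60)
        paste0(substr(x$consensus_ungapped, 1, 60), "...")
      else x$consensus_ungapped, "\n", sep = "")
  invisible(x)
}

#' Cluster a sequence set and build per-family consensus sequences
#'
#' Convenience pipeline: greedy clustering, star alignment of each
#' cluster against its centroid, majority-rule consensus.
#'
#' @inheritParams cluster_ltrs
#' @param threshold Consensus majority fraction.
#' @return List with `clusters` (the [cluster_ltrs()] table) and
#'   `consensus` (named character vector, one ungapped consensus per
#'   cluster).
#' @export
family_consensus <- function(seqs, id_threshold = 0.80, threshold = 0.7,
                             ...) {
  seqs <- .as_named_character(seqs)
  cl <- cluster_ltrs(seqs, id_threshold, ...)
  cons <- vapply(split(cl$seq_id, cl$cluster_id), function(ids) {
    cen <- cl$seq_id[cl$is_centroid & cl$seq_id %in% ids]
    msa <- align_star(seqs[ids], center = cen, ...)
    consensus_profile(msa, threshold)$consensus_ungapped
  }, character(1))
  list(clusters = cl, consensus = cons)
}
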