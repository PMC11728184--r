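#' ORF discovery and additional-ORF conservation surveys
#'
#' LTR retrotransposons carry GAG/POL, but some families encode
#' additional ORFs (aORFs) with no similarity to known retroelement
#' proteins.  This module finds ORFs in element sequences over six
#' frames (minimum length in nucleotides, optional removal of nested
#' ORFs), sweeps a family for conservation of a reference aORF protein
#' by local alignment, and reports amino-acid composition and pairwise
#' protein identity.
#'
#' @name orf-tools
NULL

.STOPS <- c("TAA", "TAG", "TGA")

.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  paste(gc[codons], collapse = "")
}

.orfs_one_strand <- function(s, strand, L, min_length, require_atg,
                             include_partial) {
  out <- list()
  for (frame in 0:2) {
    if (frame + 1L > nchar(s) - 2L) next
    starts_nt <- seq(frame + 1L, nchar(s) - 2L, by = 3L)
    codons <- substring(s, starts_nt, starts_nt + 2L)
    n <- length(codons)
    is_stop <- codons %in% .STOPS
    is_start <- if (require_atg) codons == "ATG" else !is_stop
    # segment id per codon; segments are delimited by stop codons, each
    # stop closing the segment it belongs to
    seg <- c(0L, cumsum(is_stop))[seq_len(n)] + 1L
    cand <- which(is_start & !is_stop)
    if (length(cand) == 0L) next
    first <- cand[!duplicated(seg[cand])]   # maximal ORF per segment
    stops <- which(is_stop)
    for (j in first) {
      stop_i <- if (seg[j] <= length(stops)) stops[seg[j]] else NA
      partial <- is.na(stop_i)
      if (partial && !include_partial) next
      last <- if (partial) n else stop_i
      nt_len <- (last - j + 1L) * 3L
      if (nt_len < min_length) next
      cod <- codons[j:(if (partial) last else last - 1L)]
      s0 <- starts_nt[j] - 1L               # 0-based on scanned strand
      e0 <- starts_nt[last] + 2L
      out[[length(out) + 1L]] <- data.frame(
        start = if (strand == "+") s0 else L - e0,
        end = if (strand == "+") e0 else L - s0,
        strand = strand, frame = frame,
        nt_length = nt_len, aa_length = length(cod),
        partial = partial,
        protein = .translate_codons(cod),
        stringsAsFactors = FALSE
      )
    }
  }
  out
}

#' Find open reading frames in a nucleotide sequence
#'
#' Scans all six frames (or forward-only); an ORF runs from a start codon
#' to the first in-frame stop, the stop codon included in the span but
#' excluded from the protein.  Per frame segment (between consecutive
#' stops) the maximal ORF — from the first eligible start codon — is
#' reported.  Minus-strand ORFs are reported in forward-strand
#' coordinates (0-based half-open) with strand `"-"`.
#'
#' @param seq Nucleotide sequence (string or `DNAString`).
#' @param min_length Minimum ORF length in nucleotides (stop included),
#'   default 300 (i.e. at least 99 codons + stop).
#' @param both_strands Scan the reverse complement too, default `TRUE`.
#' @param require_atg Require an ATG start, default `TRUE`; when `FALSE`
#'   any non-stop codon can open an ORF.
#' @param include_partial Report ORFs running off the sequence end
#'   without a stop, flagged `partial = TRUE`; default `FALSE`.
#' @return data.frame `start`, `end`, `strand`, `frame` (0/1/2 on the
#'   scanned strand), `nt_length`, `aa_length`, `partial`, `protein`
#'   (no stop symbol), sorted by start.  Empty (0-row) when nothing
#'   qualifies.
#' @export
find_orfs <- function(seq, min_length = 300, both_strands = TRUE,
                      require_atg = TRUE, include_partial = FALSE) {
  s <- .valid_dna(seq, "seq")
  L <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      nt_length = integer(0), aa_length = integer(0),
                      partial = logical(0), protein = character(0),
                      stringsAsFactors = FALSE)
  if (L < max(min_length, 3L)) return(empty)
  res <- .orfs_one_strand(s, "+", L, min_length, require_atg,
                          include_partial)
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    res <- c(res, .orfs_one_strand(rc, "-", L, min_length, require_atg,
                                   include_partial))
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$strand, out$frame), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove nested ORFs
#'
#' An ORF whose `[start, end)` interval is fully contained within another
#' retained ORF's interval on the same strand is dropped.  Containment is
#' resolved longest-first; ties broken by start, then frame.  ORFs on
#' opposite strands never mask each other.
#'
#' @param orfs data.frame from [find_orfs()].
#' @return The retained rows, sorted by start.
#' @export
remove_nested_orfs <- function(orfs) {
  if (nrow(orfs) <= 1L) return(orfs)
  ord <- order(-orfs$nt_length, orfs$start, orfs$frame)
  keep <- logical(nrow(orfs))
  for (i in ord) {
    ret <- which(keep & orfs$strand == orfs$strand[i])
    contained <- any(orfs$start[ret] <= orfs$start[i] &
                     orfs$end[i] <= orfs$end[ret])
    if (!contained) keep[i] <- TRUE
  }
  out <- orfs[keep, , drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Survey a family for conservation of an additional ORF
#'
#' For each member sequence, ORFs are predicted ([find_orfs()], nested
#' removal optional), translated, and locally aligned against the
#' reference aORF protein (BLOSUM62 Smith-Waterman, standing in for a
#' BLASTP search).  A member carries the aORF when any of its ORFs
#' reaches both the identity and the reference-coverage threshold; the
#' best hit per member is recorded.
#'
#' @param reference_protein Amino-acid sequence of the reference aORF.
#' @param members Named nucleotide sequences of family members.
#' @param min_identity,min_coverage Percent thresholds, default 50/50.
#'   Coverage is the fraction of the reference protein covered by the
#'   local alignment.
#' @param family_id Label for the output.
#' @param drop_nested Apply [remove_nested_orfs()] first, default `TRUE`.
#' @param ... Passed to [find_orfs()] (e.g. `min_length`).
#' @return An `aorf_survey` list: `family_id`, `n_members`,
#'   `n_with_aorf`, `fraction` (percent), and `hits` — one row per member
#'   with best identity/coverage, ORF coordinates and the `carrier` call.
#' @export
survey_aorf <- function(reference_protein, members, min_identity = 50,
                        min_coverage = 50, family_id = "family",
                        drop_nested = TRUE, ...) {
  ref <- toupper(as.character(reference_protein))
  members <- .as_named_character(members)
  if (length(members) == 0L) stop("empty member set", call. = FALSE)

  orf_tabs <- lapply(names(members), function(nm) {
    orfs <- find_orfs(members[[nm]], ...)
    if (drop_nested) orfs <- remove_nested_orfs(orfs)
    if (nrow(orfs)) cbind(member_id = nm, orfs, stringsAsFactors = FALSE)
  })
  orf_tab <- do.call(rbind, orf_tabs)

  no_hit <- data.frame(identity = 0, coverage = 0,
                       orf_start = NA_integer_, orf_end = NA_integer_,
                       strand = NA_character_, carrier = FALSE,
                       stringsAsFactors = FALSE)
  if (is.null(orf_tab) || nrow(orf_tab) == 0L) {
    hits <- cbind(member_id = names(members), no_hit, row.names = NULL)
  } else {
    # one vectorised local-alignment sweep over every predicted ORF
    gp <- .gap_params(-11, -1)
    blosum <- get(utils::data("BLOSUM62", package = "Biostrings",
                              envir = environment()))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(orf_tab$protein), Biostrings::AAString(ref),
      type = "local", substitutionMatrix = blosum,
      gapOpening = gp$opening, gapExtension = gp$extension)
    n_aln <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
    orf_tab$identity <- ifelse(n_aln > 0,
                               100 * Biostrings::nmatch(aln) / n_aln, 0)
    orf_tab$coverage <- 100 * n_aln / nchar(ref)
    orf_tab$pass <- orf_tab$identity >= min_identity &
      orf_tab$coverage >= min_coverage
    # best hit per member: passing hits first, then identity, coverage
    ord <- order(orf_tab$member_id, -orf_tab$pass, -orf_tab$identity,
                 -orf_tab$coverage)
    best <- orf_tab[ord, ][!duplicated(orf_tab$member_id[ord]), ]
    idx <- match(names(members), best$member_id)
    hits <- data.frame(
      member_id = names(members),
      identity = ifelse(is.na(idx), 0, best$identity[idx]),
      coverage = ifelse(is.na(idx), 0, best$coverage[idx]),
      orf_start = best$start[idx], orf_end = best$end[idx],
      strand = best$strand[idx],
      carrier = !is.na(idx) & best$pass[idx],
      stringsAsFactors = FALSE)
  }
  n_with <- sum(hits$carrier)
  structure(list(
    family_id = family_id, n_members = length(members),
    n_with_aorf = n_with,
    fraction = 100 * n_with / length(members),
    hits = hits,
    min_identity = min_identity, min_coverage = min_coverage
  ), class = "aorf_survey")
}

#' @export
print.aorf_survey <- function(x, ...) {
  cat(sprintf(
    "<aorf_survey> %s: %d of %d members carry the aORF (%.1f%%)\n",
    x$family_id, x$n_with_aorf, x$n_members, x$fraction))
  invisible(x)
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid composition of a protein
#'
#' @param protein Amino-acid sequence.
#' @return data.frame `residue`, `count`, `fraction` over the 20 standard
#'   residues (fractions sum to 1 over the standard residues); any
#'   non-standard symbols are tallied in the `nonstandard` attribute and
#'   excluded from the denominator.
#' @export
aa_composition <- function(protein) {
  p <- toupper(as.character(protein))
  if (nchar(p) == 0L) stop("empty protein", call. = FALSE)
  chars <- .split_chars(p)
  std <- chars[chars %in% .AA20]
  counts <- table(factor(std, levels = .AA20))
  out <- data.frame(residue = .AA20, count = as.integer(counts),
                    fraction = as.numeric(counts) / length(std),
                    stringsAsFactors = FALSE)
  ns <- chars[!chars %in% .AA20]
  attr(out, "nonstandard") <- if (length(ns)) table(ns) else NULL
  out
}

#' Pairwise global identity matrix for a protein set
#'
#' @param proteins Named amino-acid sequences (at least two).
#' @param gap_open,gap_extend Gap penalties for the global BLOSUM62
#'   alignment.
#' @return Symmetric percent-identity matrix with a 100 diagonal.
#' @export
identity_matrix <- function(proteins, gap_open = -11, gap_extend = -1) {
  proteins <- .as_named_character(proteins)
  n <- length(proteins)
  if (n < 2L) stop("need at least two proteins", call. = FALSE)
  gp <- .gap_params(gap_open, gap_extend)
  blosum <- get(utils::data("BLOSUM62", package = "Biostrings",
                            envir = environment()))
  m <- matrix(100, n, n, dimnames = list(names(proteins),
                                         names(proteins)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(proteins[[i]]),
        Biostrings::AAString(proteins[[j]]),
        type = "global", substitutionMatrix = blosum,
        gapOpening = gp$opening, gapExtension = gp$extension)
      pair <- .new_aligned_pair(
        as.character(Biostrings::alignedPattern(aln)),
        as.character(Biostrings::alignedSubject(aln)),
        Biostrings::score(aln), "global")
      m[i, j] <- m[j, i] <- percent_identity(pair)$identity
    }
  }
  m
}
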