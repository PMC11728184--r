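#' Pairwise and star alignment utilities
#'
#' Global (Needleman-Wunsch, affine gaps) and local (Smith-Waterman,
#' BLOSUM62) alignment wrappers used throughout the pipeline: LTR pair
#' alignment for dating, query-vs-database alignment for 80-80-80 family
#' assignment, and protein alignment for additional-ORF surveys.  The
#' dynamic programming engine is [Biostrings::pairwiseAlignment()]; these
#' wrappers fix the scoring conventions and return a light-weight
#' `aligned_pair` object holding the two gapped strings.
#'
#' Gap scoring convention: a gap run of length L scores
#' `gap_open + (L - 1) * gap_extend` (both negative), i.e. the first gapped
#' position pays the opening penalty.
#'
#' @name alignment
NULL

.valid_dna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  if (length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGTN]", x))
    stop(what, " contains symbols outside {A,C,G,T,N}", call. = FALSE)
  x
}

# 5x5 substitution matrix over A,C,G,T,N; N columns score 0 so ambiguity
# never attracts nor repels the traceback.
.dna_submat <- function(match, mismatch) {
  alpha <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(alpha, alpha))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

.gap_params <- function(gap_open, gap_extend) {
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be <= 0", call. = FALSE)
  if (abs(gap_open) < abs(gap_extend))
    stop("|gap_open| must be >= |gap_extend|", call. = FALSE)
  # Biostrings charges gapOpening + L * gapExtension for a length-L run
  list(opening = abs(gap_open) - abs(gap_extend), extension = abs(gap_extend))
}

.new_aligned_pair <- function(a, b, score, type) {
  stopifnot(nchar(a) == nchar(b))
  structure(
    list(seq_a_aligned = a, seq_b_aligned = b, score = score, type = type),
    class = "aligned_pair"
  )
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("<aligned_pair> (", x$type, "), score ", x$score,
      ", ", nchar(x$seq_a_aligned), " columns\n", sep = "")
  if (nchar(x$seq_a_aligned) <= 100) {
    cat(" a: ", x$seq_a_aligned, "\n b: ", x$seq_b_aligned, "\n", sep = "")
  }
  invisible(x)
}

#' Global alignment of two nucleotide sequences
#'
#' Optimal Needleman-Wunsch alignment under affine gap penalties.  Used to
#' align the 5' and 3' LTR of an element before transition/transversion
#' counting, and for identity/coverage computation in family assignment.
#'
#' @param seq_a,seq_b Nucleotide sequences (strings or `DNAString`),
#'   alphabet A/C/G/T/N.
#' @param match,mismatch Match and mismatch scores.
#' @param gap_open,gap_extend Gap penalties (non-positive); a gap run of
#'   length L scores `gap_open + (L - 1) * gap_extend`.
#' @return An `aligned_pair`: gapped strings `seq_a_aligned` /
#'   `seq_b_aligned` of equal length plus the optimal `score`.
#' @examples
#' align_global("ACGT", "ACGA")
#' @export
align_global <- function(seq_a, seq_b, match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -1) {
  a <- .valid_dna(seq_a, "seq_a")
  b <- .valid_dna(seq_b, "seq_b")
  gp <- .gap_params(gap_open, gap_extend)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = .dna_submat(match, mismatch),
    gapOpening = gp$opening, gapExtension = gp$extension
  )
  .new_aligned_pair(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)),
    Biostrings::score(aln), "global"
  )
}

#' Local protein alignment (Smith-Waterman, BLOSUM62)
#'
#' Used by [survey_aorf()] to search predicted ORF proteins against a
#' reference additional-ORF protein, in place of a BLASTP search.
#'
#' @param query,subject Amino-acid sequences (strings or `AAString`).
#' @param gap_open,gap_extend Gap penalties, defaults mirror BLASTP
#'   (-11 / -1).
#' @return An `aligned_pair` covering the locally aligned region.
#' @export
align_local_protein <- function(query, subject, gap_open = -11,
                                gap_extend = -1) {
  q <- toupper(as.character(query))
  s <- toupper(as.character(subject))
  if (nchar(q) == 0L || nchar(s) == 0L)
    stop("empty protein sequence", call. = FALSE)
  gp <- .gap_params(gap_open, gap_extend)
  blosum <- get(utils::data("BLOSUM62", package = "Biostrings",
                            envir = environment()))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s),
    type = "local", substitutionMatrix = blosum,
    gapOpening = gp$opening, gapExtension = gp$extension
  )
  out <- .new_aligned_pair(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)),
    Biostrings::score(aln), "local"
  )
  out$query_length <- nchar(q)
  out$subject_length <- nchar(s)
  out
}

.split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Count transitions and transversions in an aligned pair
#'
#' Columns containing a gap or an N in either row are excluded from the
#' comparable sites. A<->G and C<->T differences are transitions; every
#' other differing pair is a transversion.
#'
#' @param pair An `aligned_pair` from [align_global()].
#' @return A list with `transitions`, `transversions`, `n_sites`, and the
#'   proportions `P` (= transitions / n_sites) and `Q`
#'   (= transversions / n_sites).
#' @export
count_substitutions <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  a <- .split_chars(pair$seq_a_aligned)
  b <- .split_chars(pair$seq_b_aligned)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  diff <- a != b
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- sum(diff & (pur[a] == pur[b]))
  tv <- sum(diff) - ts
  list(
    transitions = ts, transversions = tv, n_sites = n,
    P = if (n > 0) ts / n else 0,
    Q = if (n > 0) tv / n else 0
  )
}

#' Percent identity and query coverage of an aligned pair
#'
#' Identity is computed over the aligned region (columns where both rows
#' carry a base); coverage is the fraction of the query's residues that
#' fall inside that region.  These are the two quantities thresholded by
#' the 80-80-80 family rule.
#'
#' @param pair An `aligned_pair`.
#' @param query Which row is the query, `"a"` (default) or `"b"`.
#' @return A list with `identity` and `coverage`, both in percent, plus
#'   the column counts used.
#' @export
percent_identity <- function(pair, query = c("a", "b")) {
  stopifnot(inherits(pair, "aligned_pair"))
  query <- match.arg(query)
  a <- .split_chars(pair$seq_a_aligned)
  b <- .split_chars(pair$seq_b_aligned)
  both <- a != "-" & b != "-"
  n_aln <- sum(both)
  n_match <- sum(both & a == b)
  qrow <- if (query == "a") a else b
  qlen <- if (!is.null(pair$query_length) && query == "a")
    pair$query_length else sum(qrow != "-")
  list(
    identity = if (n_aln > 0) 100 * n_match / n_aln else 0,
    coverage = if (qlen > 0) 100 * n_aln / qlen else 0,
    aligned_columns = n_aln, matches = n_match, query_length = qlen
  )
}

#' Star multiple alignment against a centre sequence
#'
#' Desk-scale stand-in for an external multiple aligner: every sequence is
#' globally aligned to the centre (by default the longest sequence) and
#' the pairwise alignments are merged on the centre's coordinates, padding
#' insertions per slot.  Adequate for the near-identical within-family
#' sequences it is applied to; not a general MSA.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of sequences.
#' @param center Name or index of the centre sequence; default = longest.
#' @param ... Scoring parameters passed to [align_global()].
#' @return Named character vector of gapped rows, all equal length, in
#'   input order.
#' @export
align_star <- function(seqs, center = NULL, ...) {
  seqs <- .as_named_character(seqs)
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  if (length(seqs) == 1L) return(seqs)
  if (is.null(center)) {
    center <- names(seqs)[order(-nchar(seqs), names(seqs))][1L]
  } else if (is.numeric(center)) {
    center <- names(seqs)[center]
  }
  cen <- seqs[[center]]
  clen <- nchar(cen)
  others <- setdiff(names(seqs), center)

  # per pairwise alignment: insertion lengths at each of clen+1 slots and
  # the other row's character at each centre base
  ins_max <- integer(clen + 1L)
  rows <- list()
  for (nm in others) {
    pr <- align_global(cen, seqs[[nm]], ...)
    ca <- .split_chars(pr$seq_a_aligned)  # centre row
    cb <- .split_chars(pr$seq_b_aligned)
    pos <- 0L                    # centre bases consumed
    ins <- integer(clen + 1L)    # insertion length per slot
    base_chr <- character(clen)  # other-row char under each centre base
    ins_chr <- vector("list", clen + 1L)
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        ins[pos + 1L] <- ins[pos + 1L] + 1L
        ins_chr[[pos + 1L]] <- c(ins_chr[[pos + 1L]], cb[k])
      } else {
        pos <- pos + 1L
        base_chr[pos] <- cb[k]
      }
    }
    ins_max <- pmax(ins_max, ins)
    rows[[nm]] <- list(base = base_chr, ins = ins_chr)
  }

  pad <- function(chars, width) {
    c(chars, rep("-", width - length(chars)))
  }
  emit <- function(base_chr, ins_chr) {
    out <- character(0)
    for (p in 0:clen) {
      if (ins_max[p + 1L] > 0) {
        got <- if (is.null(ins_chr)) NULL else ins_chr[[p + 1L]]
        out <- c(out, pad(if (is.null(got)) character(0) else got,
                          ins_max[p + 1L]))
      }
      if (p < clen) out <- c(out, base_chr[p + 1L])
    }
    paste(out, collapse = "")
  }

  res <- character(length(seqs))
  names(res) <- names(seqs)
  res[center] <- emit(.split_chars(cen), NULL)
  for (nm in others) res[nm] <- emit(rows[[nm]]$base, rows[[nm]]$ins)
  res[names(seqs)]
}

.as_named_character <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    out <- as.character(seqs)
  } else {
    out <- as.character(seqs)
    names(out) <- names(seqs)
  }
  if (length(out) == 0L) return(character(0))
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
    names(out) <- paste0("seq", seq_along(out))
  toupper(out)
}
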