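#' Kimura two-parameter LTR insertion dating
#'
#' The two LTRs of a retrotransposon are identical at the moment of
#' insertion and accumulate substitutions independently afterwards, so
#' their divergence clocks the element's age.  The pipeline aligns each
#' LTR pair, counts transition (P) and transversion (Q) proportions over
#' the comparable sites, corrects for multiple hits with the Kimura
#' two-parameter distance
#' \deqn{K = -\tfrac{1}{2}\,\ln\big((1-2P-Q)\sqrt{1-2Q}\big)}
#' and converts distance to time with \eqn{T = K / (2r)}, where r is the
#' per-site per-year substitution rate (default 1.0e-8).
#'
#' @name ltr-dating
NULL

#' Kimura two-parameter distance
#'
#' @param P Transition proportion (transitions / comparable sites).
#' @param Q Transversion proportion.
#' @return K, the estimated substitutions per site.  Errors with a
#'   saturation message when the log arguments leave the domain
#'   (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`), i.e. when divergence is too
#'   high for the correction to be defined.
#' @param element_id Optional label used in the saturation error message.
#' @examples
#' k2p_distance(0.1, 0.05)   # 0.1701812
#' @export
k2p_distance <- function(P, Q, element_id = NULL) {
  stopifnot(is.numeric(P), is.numeric(Q), length(P) == length(Q))
  if (any(P < 0 | Q < 0 | P > 1 | Q > 1))
    stop("P and Q must lie in [0, 1]", call. = FALSE)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  bad <- w1 <= 0 | w2 <= 0
  if (any(bad)) {
    who <- if (is.null(element_id)) which(bad)[1L] else element_id[bad][1L]
    stop(sprintf(
      "K2P saturation for element '%s': P=%g, Q=%g leave the log domain",
      as.character(who), P[bad][1L], Q[bad][1L]), call. = FALSE)
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Insertion time from K2P distance
#'
#' @param K K2P distance (substitutions/site), `>= 0`.
#' @param r Substitution rate per site per year, default `1.0e-8`.
#' @return Insertion time in Mya: `K / (2 * r) / 1e6`.
#' @examples
#' insertion_time(0.02)  # 1 Mya
#' @export
insertion_time <- function(K, r = 1.0e-8) {
  stopifnot(is.numeric(K), is.numeric(r), length(r) == 1L)
  if (any(K < 0)) stop("K must be >= 0", call. = FALSE)
  if (r <= 0) stop("substitution rate r must be > 0", call. = FALSE)
  K / (2 * r) / 1e6
}

#' Date a set of LTR pairs
#'
#' Aligns each 5'/3' LTR pair, counts substitutions, and returns the K2P
#' distance and insertion time per element.  Pairs may be supplied either
#' as two parallel sequence sets or pre-aligned (gapped, equal length)
#' with `aligned = TRUE`, mirroring a pipeline where an external aligner
#' produced the pairs.
#'
#' @param ltr5,ltr3 Character vectors / `DNAStringSet`s of equal length
#'   holding the paired LTR sequences.
#' @param element_id Element labels; default names of `ltr5` or `elem_i`.
#' @param r Substitution rate per site per year.
#' @param aligned If `TRUE` the inputs are already gapped alignments and
#'   the aligner is skipped.
#' @param ... Scoring parameters passed to [align_global()].
#' @return A data.frame with columns `element_id`, `n_sites`,
#'   `transitions`, `transversions`, `P`, `Q`, `K`, `T_mya`.  Saturated
#'   pairs (outside the K2P domain) get `NA` in `K`/`T_mya` with a
#'   warning naming the element.
#' @export
date_ltr_pairs <- function(ltr5, ltr3, element_id = NULL, r = 1.0e-8,
                           aligned = FALSE, ...) {
  l5 <- .as_named_character(ltr5)
  l3 <- .as_named_character(ltr3)
  if (length(l5) != length(l3))
    stop("ltr5 and ltr3 must have the same length", call. = FALSE)
  if (is.null(element_id)) {
    element_id <- if (!is.null(names(ltr5))) names(l5)
                  else paste0("elem_", seq_along(l5))
  }
  res <- lapply(seq_along(l5), function(i) {
    pair <- if (aligned) {
      .new_aligned_pair(l5[[i]], l3[[i]], NA_real_, "prealigned")
    } else {
      align_global(l5[[i]], l3[[i]], ...)
    }
    cs <- count_substitutions(pair)
    K <- tryCatch(k2p_distance(cs$P, cs$Q, element_id[i]),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NA_real_
                  })
    data.frame(
      element_id = element_id[i], n_sites = cs$n_sites,
      transitions = cs$transitions, transversions = cs$transversions,
      P = cs$P, Q = cs$Q, K = K,
      T_mya = if (is.na(K)) NA_real_ else insertion_time(K, r),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}
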