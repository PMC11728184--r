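# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: the Fisher oracle enumerates tables with
# log-binomial coefficients, the alignment oracle enumerates every
# alignment path, the K2P oracle is the published closed form evaluated
# inline.

# Two-sided Fisher p by direct enumeration over the conditional support,
# point probabilities from lchoose (not dhyper).
oracle_fisher <- function(a, b, c, d, tie_tol = 1e-7) {
  R1 <- a + b; C1 <- a + c; N <- a + b + c + d
  sup <- max(0, R1 + C1 - N):min(R1, C1)
  lp <- lchoose(C1, sup) + lchoose(N - C1, R1 - sup) - lchoose(N, R1)
  p <- exp(lp)
  min(1, sum(p[p <= p[sup == a] * (1 + tie_tol)]))
}

# Optimal global affine-gap alignment score by exhaustive enumeration of
# all alignment paths (first gap position costs gap_open, each further
# one gap_extend).  Exponential; only for tiny sequences.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = -2, gap_extend = -1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- -Inf
  recur <- function(i, j, prev, acc) {
    if (i == length(a) && j == length(b)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i < length(a) && j < length(b)) {
      s <- if (a[i + 1] == b[j + 1]) match else mismatch
      recur(i + 1, j + 1, "d", acc + s)
    }
    if (i < length(a))
      recur(i + 1, j, "a",
            acc + if (prev == "a") gap_extend else gap_open)
    if (j < length(b))
      recur(i, j + 1, "b",
            acc + if (prev == "b") gap_extend else gap_open)
  }
  recur(0, 0, "d", 0)
  best
}

# Rand index between two partitions given as label vectors.
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  mean(same_x == same_y)
}

# Expected K2P transition/transversion difference proportions after
# total distance d with ts:tv odds kappa (Kimura's closed form).
oracle_k2p_pq <- function(d, kappa) {
  alpha <- kappa / (kappa + 1)
  beta <- 1 / (2 * (kappa + 1))
  c(P = 0.25 + 0.25 * exp(-4 * beta * d) -
        0.5 * exp(-2 * (alpha + beta) * d),
    Q = 0.5 - 0.5 * exp(-4 * beta * d))
}

# Jaccard index of two interval sets on one chromosome, given as
# data.frames with start/end (0-based half-open).
interval_jaccard <- function(x, y) {
  ix <- IRanges::IRanges(start = x$start + 1, end = x$end)
  iy <- IRanges::IRanges(start = y$start + 1, end = y$end)
  inter <- sum(IRanges::width(IRanges::intersect(ix, iy)))
  uni <- sum(IRanges::width(IRanges::union(ix, iy)))
  if (uni == 0) return(1)
  inter / uni
}

# deterministic random DNA for fixtures
rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions of a sequence with a different base
mutate_exact <- function(seq, k, seed = 1) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
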