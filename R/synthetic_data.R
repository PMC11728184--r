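#' Synthetic study-data generator
#'
#' Generates every input the pipeline consumes, with known ground truth:
#' a toy genome carrying planted LTR retrotransposons whose LTR pairs
#' have diverged under the Kimura two-parameter substitution process, a
#' clustered centromeric repeat-hit track, gene annotation, PS+/PS-
#' eccDNA read-count tables with known enriched elements, multi-accession
#' TIP tables with controlled compartment bias and sharing structure, and
#' nucleotide families carrying a conserved additional ORF.  All
#' generators are deterministic given their seed.
#'
#' LTR divergence is a model distance: each LTR copy is evolved for half
#' the configured divergence under the exact K2P transition matrix (no
#' indels), so the K2P estimator applied downstream is consistent for the
#' configured value.  `ts_tv_ratio` is the transition:transversion odds
#' per substitution event (transition probability kappa/(kappa+1)).
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: two 10-Mb
#' chromosomes with a 20% centromeric block, 1-kb LTRs at a spread of
#' pairwise divergences, a 20-fold eccDNA enrichment over a 50-read
#' background, a 12-accession TIP panel where 85% of TIPs are private to
#' one or two accessions, and a 523-member family of which 500 carry the
#' additional ORF.
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes Number of chromosomes.
#' @param n_elements Planted LTR elements (across all chromosomes).
#' @param ltr_length LTR length, bp.
#' @param internal_length Internal (between-LTR) region length, bp.
#' @param divergence_per_pair K2P distances between LTR pairs
#'   (substitutions/site), recycled over elements; each in `[0, 0.5)`.
#' @param ts_tv_ratio Transition:transversion odds kappa (> 0).
#' @param centromere_fraction Centromere length as a fraction of the
#'   chromosome (`< 0.5`).
#' @param hit_density_centromeric,hit_density_arm Repeat hits per 100 kb
#'   inside / outside the centromere.
#' @param n_genes Genes to scatter per genome.
#' @param gene_length Gene span, bp.
#' @param n_accessions TIP panel size.
#' @param enrichment_factor PS+ count multiplier for truly circular
#'   elements.
#' @param ecc_background Background read count per element per library.
#' @param ecc_enriched_fraction Fraction of elements that are truly
#'   eccDNA-producing.
#' @param off_target_reads Library reads not on any element (added to
#'   the totals of both libraries).
#' @param n_tips TIPs to simulate.
#' @param sharing_le2 Probability a TIP is present in one or two
#'   accessions.
#' @param tip_group_peri_bias Named per-group probability that a TIP
#'   falls in the centromere/pericentromere compartment.
#' @param aorf_family_size,aorf_presence_rate Family size and carrier
#'   fraction for the additional-ORF family (defaults 523 and 500/523).
#' @param seed Integer seed; identical config + seed reproduces outputs
#'   byte for byte.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e7,
                       n_chromosomes = 2,
                       n_elements = 20,
                       ltr_length = 1000,
                       internal_length = 3000,
                       divergence_per_pair = c(0.01, 0.02, 0.05, 0.10),
                       ts_tv_ratio = 2,
                       centromere_fraction = 0.2,
                       hit_density_centromeric = 30,
                       hit_density_arm = 0.5,
                       n_genes = 100,
                       gene_length = 3000,
                       n_accessions = 12,
                       enrichment_factor = 20,
                       ecc_background = 50,
                       ecc_enriched_fraction = 0.2,
                       off_target_reads = 5000,
                       n_tips = 1000,
                       sharing_le2 = 0.85,
                       tip_group_peri_bias = c(tekay_g1 = 0.8,
                                               tekay_g2 = 0.1,
                                               tekay_g3 = 0.8),
                       aorf_family_size = 523,
                       aorf_presence_rate = 500 / 523,
                       seed = 42) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      genome_length > 0, n_chromosomes >= 1, n_elements >= 0,
      ltr_length > 0, internal_length >= 0,
      all(divergence_per_pair >= 0), all(divergence_per_pair < 0.5),
      ts_tv_ratio > 0,
      centromere_fraction > 0, centromere_fraction < 0.5,
      hit_density_centromeric >= 0, hit_density_arm >= 0,
      n_accessions >= 2, enrichment_factor >= 0, ecc_background >= 0,
      ecc_enriched_fraction >= 0, ecc_enriched_fraction <= 1,
      sharing_le2 >= 0, sharing_le2 <= 1,
      all(tip_group_peri_bias >= 0), all(tip_group_peri_bias <= 1),
      aorf_presence_rate >= 0, aorf_presence_rate <= 1,
      length(seed) == 1, is.finite(seed)
    )
  })
  if (2 * cfg$ltr_length + cfg$internal_length > cfg$genome_length)
    stop("element footprint exceeds chromosome length", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Random nucleotide sequence
#' @param n Length in bp.
#' @return An uppercase A/C/G/T string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Expected K2P transition/transversion proportions at a given distance
#'
#' Closed-form probabilities that a site differs by a transition (P) or a
#' transversion (Q) after evolving a total K2P distance `d` with
#' transition:transversion odds `kappa`: with instantaneous rates scaled
#' so that alpha + 2 beta = 1 (alpha = kappa/(kappa+1)),
#' `P = 1/4 + 1/4 exp(-4 beta d) - 1/2 exp(-2 (alpha+beta) d)` and
#' `Q = 1/2 - 1/2 exp(-4 beta d)`.
#'
#' @param d K2P distance (expected substitutions/site, multiple hits
#'   included).
#' @param kappa ts:tv odds; `Inf` allowed (no transversions).
#' @return List with `P`, `Q`, and the per-event probabilities used by
#'   the per-site sampler.
#' @export
k2p_expected_pq <- function(d, kappa) {
  if (is.infinite(kappa)) {
    alpha <- 1; beta <- 0
  } else {
    alpha <- kappa / (kappa + 1)
    beta <- 1 / (2 * (kappa + 1))
  }
  P <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  Q <- 0.5 - 0.5 * exp(-4 * beta * d)
  list(P = P, Q = Q, alpha = alpha, beta = beta)
}

.TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
.TV_MAP1 <- c(A = "C", G = "C", C = "A", T = "A")
.TV_MAP2 <- c(A = "T", G = "T", C = "G", T = "G")

# evolve ACGT characters for K2P distance d (others left untouched)
.k2p_evolve <- function(chars, d, kappa) {
  pq <- k2p_expected_pq(d, kappa)
  idx <- which(chars %in% c("A", "C", "G", "T"))
  u <- stats::runif(length(idx))
  ts <- u < pq$P
  tv1 <- !ts & u < pq$P + pq$Q / 2
  tv2 <- !ts & !tv1 & u < pq$P + pq$Q
  chars[idx[ts]] <- .TS_MAP[chars[idx[ts]]]
  chars[idx[tv1]] <- .TV_MAP1[chars[idx[tv1]]]
  chars[idx[tv2]] <- .TV_MAP2[chars[idx[tv2]]]
  chars
}

#' Diverge an LTR into a pair of copies
#'
#' Evolves two copies of `ltr` independently, each for half the requested
#' K2P distance, under the exact K2P transition matrix (substitutions
#' only, no indels) — the generative inverse of the dating module.
#'
#' @param ltr Ancestral LTR sequence (A/C/G/T; other symbols error
#'   unless `iupac = TRUE`, in which case they are left untouched).
#' @param divergence Total K2P distance between the copies, `[0, 0.5)`.
#' @param ts_tv_ratio Transition:transversion odds kappa.
#' @param seed Optional seed (`set.seed` is called when supplied).
#' @param iupac Tolerate non-ACGT symbols, default `FALSE`.
#' @return List: `ltr_a`, `ltr_b`, the realized difference bookkeeping
#'   (`transitions`, `transversions`, `n_sites` from direct string
#'   comparison) and a `meta` record of the divergence, kappa and the
#'   kappa convention.
#' @export
mutate_ltr_pair <- function(ltr, divergence, ts_tv_ratio = 2,
                            seed = NULL, iupac = FALSE) {
  l <- toupper(as.character(ltr))
  if (nchar(l) == 0L) stop("empty LTR sequence", call. = FALSE)
  if (!iupac && grepl("[^ACGT]", l))
    stop("non-ACGT symbols in LTR (set iupac = TRUE to tolerate)",
         call. = FALSE)
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must lie in [0, 0.5)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  chars <- .split_chars(l)
  a <- if (divergence == 0) chars
       else .k2p_evolve(chars, divergence / 2, ts_tv_ratio)
  b <- if (divergence == 0) chars
       else .k2p_evolve(chars, divergence / 2, ts_tv_ratio)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  diff <- ok & a != b
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- sum(diff & unname(pur[a]) == unname(pur[b]), na.rm = TRUE)
  list(
    ltr_a = paste(a, collapse = ""),
    ltr_b = paste(b, collapse = ""),
    transitions = ts,
    transversions = sum(diff) - ts,
    n_sites = sum(ok),
    meta = list(
      divergence = divergence, ts_tv_ratio = ts_tv_ratio,
      kappa_convention =
        "ts:tv odds per substitution; P(transition) = kappa/(kappa+1)"
    )
  )
}

#' Simulate the centromeric repeat-hit track
#'
#' Poisson point process: qualifying hits (similarity 75-100%) at
#' `density_cen` per 100 kb inside the true centromere and `density_arm`
#' outside, plus a low-similarity background (40-70%) over the whole
#' chromosome that the similarity filter must discard.
#'
#' @param chrom_lengths Named chromosome lengths.
#' @param centromeres data.frame `chrom`, `start`, `end` of true
#'   centromere intervals.
#' @param density_cen,density_arm Hits per 100 kb.
#' @param noise_density Low-similarity hits per 100 kb, default 2.
#' @param hit_width Hit width in bp, default 100.
#' @param seed Optional seed.
#' @return data.frame `chrom`, `start`, `end`, `similarity` (BED-like,
#'   0-based half-open).
#' @export
simulate_centromere_hits <- function(chrom_lengths, centromeres,
                                     density_cen = 30, density_arm = 0.5,
                                     noise_density = 2, hit_width = 100,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  emit <- function(chrom, pos, lo, hi) {
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = chrom, start = floor(pos),
               end = floor(pos) + hit_width,
               similarity = stats::runif(length(pos), lo, hi),
               stringsAsFactors = FALSE)
  }
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    cen <- centromeres[centromeres$chrom == chrom, , drop = FALSE]
    cs <- if (nrow(cen)) cen$start[1] else NA
    ce <- if (nrow(cen)) cen$end[1] else NA
    if (nrow(cen)) {
      n_c <- stats::rpois(1, density_cen * (ce - cs) / 1e5)
      rows[[length(rows) + 1L]] <-
        emit(chrom, stats::runif(n_c, cs, ce - hit_width), 75, 100)
    }
    arm_len <- L - if (nrow(cen)) (ce - cs) else 0
    n_a <- stats::rpois(1, density_arm * arm_len / 1e5)
    if (n_a > 0) {
      u <- stats::runif(n_a, 0, arm_len - hit_width)
      pos <- if (nrow(cen)) ifelse(u < cs, u, u + (ce - cs)) else u
      rows[[length(rows) + 1L]] <- emit(chrom, pos, 75, 100)
    }
    n_n <- stats::rpois(1, noise_density * L / 1e5)
    rows[[length(rows) + 1L]] <-
      emit(chrom, stats::runif(n_n, 0, L - hit_width), 40, 70)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate the full synthetic genome with planted truth
#'
#' Builds random chromosome sequences, plants LTR elements (two LTR
#' copies diverged per [mutate_ltr_pair()] around a random internal
#' region), scatters genes, generates the centromeric repeat-hit track,
#' and labels a subset of elements as truly eccDNA-producing.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `elements.gff3`, `genes.gff3`, `line_hits.bed` and the truth TSVs.
#' @return List: `genome` (`DNAStringSet`), `elements` (coordinates,
#'   LTR child intervals, planted divergence, realized substitution
#'   bookkeeping, enrichment truth), `genes`, `hits`,
#'   `centromere_truth`, `chrom_lengths`, `config`.
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(L, length(chroms)), chroms)
  seqs <- lapply(chroms, function(x) random_dna(L))
  names(seqs) <- chroms

  # true centromeres
  cen_len <- round(config$centromere_fraction * L)
  cen_start <- round(stats::runif(length(chroms), 0.25 * L,
                                  0.75 * L - cen_len))
  centromere_truth <- data.frame(
    chrom = chroms, start = cen_start, end = cen_start + cen_len,
    stringsAsFactors = FALSE)

  # plant elements at non-overlapping positions
  foot <- 2 * config$ltr_length + config$internal_length
  if (foot > L) stop("element footprint exceeds chromosome length",
                     call. = FALSE)
  n <- config$n_elements
  div <- rep(config$divergence_per_pair, length.out = n)
  placed <- data.frame()
  elements <- list()
  for (i in seq_len(n)) {
    for (try in 1:200) {
      chrom <- sample(chroms, 1)
      start <- floor(stats::runif(1, 0, L - foot))
      clash <- nrow(placed) > 0 &&
        any(placed$chrom == chrom & placed$start < start + foot &
            start < placed$end)
      if (!clash) break
      if (try == 200)
        stop("could not place element ", i,
             "; too many elements for the genome", call. = FALSE)
    }
    placed <- rbind(placed, data.frame(chrom = chrom, start = start,
                                       end = start + foot))
    anc <- random_dna(config$ltr_length)
    pair <- mutate_ltr_pair(anc, div[i], config$ts_tv_ratio)
    body <- paste0(pair$ltr_a, random_dna(config$internal_length),
                   pair$ltr_b)
    substr(seqs[[chrom]], start + 1L, start + foot) <- body
    elements[[i]] <- data.frame(
      element_id = sprintf("RTE_%02d", i), chrom = chrom,
      start = start, end = start + foot,
      ltr5_start = start, ltr5_end = start + config$ltr_length,
      ltr3_start = start + foot - config$ltr_length,
      ltr3_end = start + foot,
      divergence = div[i],
      realized_transitions = pair$transitions,
      realized_transversions = pair$transversions,
      realized_sites = pair$n_sites,
      stringsAsFactors = FALSE)
  }
  elements <- if (n > 0) do.call(rbind, elements) else
    data.frame(element_id = character(0))
  if (n > 0) {
    n_enr <- round(config$ecc_enriched_fraction * n)
    elements$enriched <- seq_len(n) %in% sample(n, n_enr)
  }

  # genes scattered uniformly (may fall anywhere; the genic classifier
  # only needs intervals)
  genes <- data.frame(
    gene_id = sprintf("gene_%03d", seq_len(config$n_genes)),
    chrom = sample(chroms, config$n_genes, replace = TRUE),
    start = floor(stats::runif(config$n_genes, 0,
                               L - config$gene_length)),
    stringsAsFactors = FALSE)
  genes$end <- genes$start + config$gene_length
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  hits <- simulate_centromere_hits(
    chrom_lengths, centromere_truth,
    density_cen = config$hit_density_centromeric,
    density_arm = config$hit_density_arm)

  out <- list(
    genome = Biostrings::DNAStringSet(unlist(seqs)),
    elements = elements, genes = genes, hits = hits,
    centromere_truth = centromere_truth,
    chrom_lengths = chrom_lengths, config = config)
  if (!is.null(out_dir)) write_sim(out, out_dir)
  invisible(out)
}

#' Extract planted LTR pair sequences from a simulated genome
#'
#' @param sim Output of [simulate_genome()].
#' @return data.frame `element_id`, `ltr5`, `ltr3` (sequences pulled
#'   from the genome at the annotated child intervals).
#' @export
extract_ltr_pairs <- function(sim) {
  el <- sim$elements
  gen <- as.character(sim$genome)
  data.frame(
    element_id = el$element_id,
    ltr5 = substring(gen[el$chrom], el$ltr5_start + 1L, el$ltr5_end),
    ltr3 = substring(gen[el$chrom], el$ltr3_start + 1L, el$ltr3_end),
    stringsAsFactors = FALSE)
}

#' Simulate PS+/PS- read counts per element
#'
#' Non-enriched elements draw both library counts from the same Poisson
#' background; truly circular elements draw their PS+ count at
#' `enrichment_factor` times the background rate.  A coverage-breadth
#' proxy is attached per element from a read-occupancy model (each read
#' covers ~5% of the element).
#'
#' @param config A [sim_config()].
#' @param truth data.frame with `element_id` and logical `enriched`
#'   (e.g. `simulate_genome(config)$elements`).
#' @param seed Optional seed.
#' @return data.frame `element_id`, `count_plus`, `count_minus`,
#'   `breadth_plus`, with library totals (`total_plus`, `total_minus`)
#'   as attributes.
#' @export
simulate_ecc_counts <- function(config, truth, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            all(c("element_id", "enriched") %in% names(truth)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  bg <- config$ecc_background
  rate_plus <- bg * ifelse(truth$enriched, config$enrichment_factor, 1)
  count_plus <- stats::rpois(n, rate_plus)
  count_minus <- stats::rpois(n, bg)
  out <- data.frame(
    element_id = truth$element_id,
    count_plus = count_plus, count_minus = count_minus,
    breadth_plus = round(1 - 0.95^count_plus, 4),
    stringsAsFactors = FALSE)
  attr(out, "total_plus") <- sum(count_plus) + config$off_target_reads
  attr(out, "total_minus") <- sum(count_minus) + config$off_target_reads
  out
}

#' Simulate multi-accession TIP tables
#'
#' Three element groups with configured compartment bias: each TIP falls
#' in the centromere/pericentromere with its group's bias probability,
#' uniformly within the chosen compartment class.  Accession membership
#' produces the configured sharing spectrum (probability `sharing_le2`
#' of 1-2 carriers, otherwise uniform on 3..n).  Support-read counts are
#' negative-binomial with mass at and below the >5 filter boundary.
#'
#' @param config A [sim_config()].
#' @param ann A `centromere_annotation` describing the compartments TIPs
#'   are drawn from (e.g. [compartments_from_truth()] on the generator's
#'   centromere truth).
#' @param seed Optional seed.
#' @return data.frame (BED-like): `chrom`, `start`, `end`, `element_id`,
#'   `support_reads`, `group`, `accessions` (comma-joined),
#'   `n_accessions`, and the truth column `true_compartment_class`
#'   (`"cen_peri"` or `"arm"`).
#' @export
simulate_tips <- function(config, ann, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(ann, "centromere_annotation"))
  if (!is.null(seed)) set.seed(seed)
  groups <- names(config$tip_group_peri_bias)
  n <- config$n_tips
  acc_ids <- sprintf("acc%02d", seq_len(config$n_accessions))

  cen_peri <- ann[ann$compartment != "arm", , drop = FALSE]
  arm <- ann[ann$compartment == "arm", , drop = FALSE]
  draw_pos <- function(seg) {
    w <- seg$end - seg$start
    i <- sample(nrow(seg), 1, prob = w)
    floor(stats::runif(1, seg$start[i], seg$end[i]))
    # returns a single 0-based position; chrom looked up by caller
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    group <- groups[((i - 1L) %% length(groups)) + 1L]
    in_cp <- stats::runif(1) < config$tip_group_peri_bias[[group]]
    seg <- if (in_cp && nrow(cen_peri)) cen_peri else arm
    w <- seg$end - seg$start
    j <- sample(nrow(seg), 1, prob = w)
    pos <- floor(stats::runif(1, seg$start[j], seg$end[j]))
    k <- if (stats::runif(1) < config$sharing_le2) sample(1:2, 1)
         else sample(3:config$n_accessions, 1)
    rows[[i]] <- data.frame(
      chrom = seg$chrom[j], start = pos, end = pos + 1L,
      element_id = sprintf("%s_e%d", group, sample(5L, 1)),
      support_reads = stats::rnbinom(1, size = 2, mu = 12) + 1L,
      group = group,
      accessions = paste(sample(acc_ids, k), collapse = ","),
      n_accessions = k,
      true_compartment_class = if (in_cp) "cen_peri" else "arm",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$position <- out$start
  out
}

#' Simulate a nucleotide family carrying a conserved additional ORF
#'
#' Members are random flanking sequence around a planted ORF cassette
#' encoding a proline-rich reference protein (151 aa, 24 prolines,
#' ATG...stop).  Carriers keep the cassette with light codon-preserving
#' substitution noise (the reading frame and stops are never disrupted);
#' non-carriers have the cassette replaced by random sequence of equal
#' length.
#'
#' @param n_members Family size, default 523.
#' @param presence_rate Carrier fraction, default 500/523.
#' @param flank Flanking sequence per side, bp.
#' @param mutation_rate Per-interior-codon substitution probability in
#'   carriers, default 0.05.
#' @param seed Optional seed.
#' @return List: `members` (named sequences), `reference_protein`,
#'   `reference_cassette` (nucleotide ORF incl. stop), `truth`
#'   (`member_id`, `carrier`).
#' @export
simulate_aorf_family <- function(n_members = 523,
                                 presence_rate = 500 / 523,
                                 flank = 600, mutation_rate = 0.05,
                                 seed = NULL) {
  stopifnot(n_members >= 1, presence_rate >= 0, presence_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  aa_pool <- setdiff(.AA20, c("M", "P"))
  prot <- c("M", sample(c(rep("P", 24),
                          sample(aa_pool, 126, replace = TRUE))))
  codon_table <- split(names(Biostrings::GENETIC_CODE),
                       unname(Biostrings::GENETIC_CODE))
  pick_codon <- function(aa) {
    opts <- codon_table[[aa]]
    opts[sample(length(opts), 1)]
  }
  cassette_codons <- vapply(prot, pick_codon, character(1))
  cassette_codons[1] <- "ATG"
  cassette <- paste(c(cassette_codons, "TAA"), collapse = "")

  n_car <- round(presence_rate * n_members)
  carrier <- seq_len(n_members) %in% sample(n_members, n_car)
  members <- character(n_members)
  for (i in seq_len(n_members)) {
    core <- if (carrier[i]) {
      cods <- cassette_codons
      # interior codons only; resampled codons are never stops, so the
      # planted ORF always survives in carriers
      hit <- which(stats::runif(length(cods) - 1) < mutation_rate) + 1L
      for (j in hit) {
        repeat {
          cod <- .split_chars(cods[j])
          pos <- sample(3L, 1)
          cod[pos] <- sample(setdiff(c("A", "C", "G", "T"), cod[pos]), 1)
          cod <- paste(cod, collapse = "")
          if (!cod %in% .STOPS) break
        }
        cods[j] <- cod
      }
      paste(c(cods, "TAA"), collapse = "")
    } else {
      random_dna(nchar(cassette))
    }
    members[i] <- paste0(random_dna(flank), core, random_dna(flank))
  }
  names(members) <- sprintf("member_%03d", seq_len(n_members))
  list(
    members = members,
    reference_protein = paste(prot, collapse = ""),
    reference_cassette = cassette,
    truth = data.frame(member_id = names(members), carrier = carrier,
                       stringsAsFactors = FALSE)
  )
}

#' Write simulated data to standard file formats
#'
#' Emits `genome.fa`, `elements.gff3` (element features with `ltr5` /
#' `ltr3` children), `genes.gff3`, `line_hits.bed` (score = similarity),
#' and plain-TSV truth tables into `dir`.
#'
#' @param sim Output of [simulate_genome()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))

  el <- sim$elements
  if (nrow(el) > 0) {
    gr <- GenomicRanges::GRanges(
      rep(el$chrom, 3),
      IRanges::IRanges(
        start = c(el$start, el$ltr5_start, el$ltr3_start) + 1L,
        end = c(el$end, el$ltr5_end, el$ltr3_end)),
      type = rep(c("LTR_retrotransposon", "long_terminal_repeat",
                   "long_terminal_repeat"), each = nrow(el)),
      ID = c(el$element_id, paste0(el$element_id, "_ltr5"),
             paste0(el$element_id, "_ltr3")),
      Parent = c(rep(NA_character_, nrow(el)),
                 el$element_id, el$element_id))
    rtracklayer::export(gr, file.path(dir, "elements.gff3"),
                        format = "gff3")
  }
  gg <- GenomicRanges::GRanges(
    sim$genes$chrom,
    IRanges::IRanges(start = sim$genes$start + 1L, end = sim$genes$end),
    type = "gene", ID = sim$genes$gene_id)
  rtracklayer::export(gg, file.path(dir, "genes.gff3"), format = "gff3")

  h <- sim$hits
  utils::write.table(
    data.frame(h$chrom, h$start, h$end, ".", round(h$similarity, 2)),
    file.path(dir, "line_hits.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(el, file.path(dir, "elements_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$centromere_truth,
                     file.path(dir, "centromere_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
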