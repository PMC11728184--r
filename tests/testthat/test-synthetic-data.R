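small_cfg <- function(...) {
  defaults <- list(genome_length = 2e5, n_chromosomes = 2,
                   n_elements = 4, ltr_length = 300,
                   internal_length = 500, n_genes = 10, n_tips = 50,
                   seed = 123)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("identical config and seed reproduce the simulation exactly", {
  s1 <- simulate_genome(small_cfg())
  s2 <- simulate_genome(small_cfg())
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$elements, s2$elements)
  expect_identical(s1$hits, s2$hits)
  s3 <- simulate_genome(small_cfg(seed = 124))
  expect_false(identical(as.character(s1$genome),
                         as.character(s3$genome)))
})

test_that("zero divergence gives identical LTR copies; kappa limit kills tv", {
  anc <- rdna(500, seed = 8)
  p0 <- mutate_ltr_pair(anc, 0, 2)
  expect_identical(p0$ltr_a, anc)
  expect_identical(p0$ltr_b, anc)

  sim <- simulate_genome(small_cfg(divergence_per_pair = 0))
  pairs <- extract_ltr_pairs(sim)
  expect_identical(pairs$ltr5, pairs$ltr3)

  set.seed(2)
  pinf <- mutate_ltr_pair(rdna(5000), 0.2, ts_tv_ratio = Inf)
  expect_equal(pinf$transversions, 0)
  expect_gt(pinf$transitions, 0)
})

test_that("realized divergence matches the K2P model expectation", {
  # binomial oracle: at total distance d the per-site difference
  # probability is P(d) + Q(d) from Kimura's closed form
  set.seed(77)
  d <- 0.04; kappa <- 2; n_rep <- 200; len <- 1000
  frac <- replicate(n_rep, {
    p <- mutate_ltr_pair(rdna(len), d, kappa)
    (p$transitions + p$transversions) / p$n_sites
  })
  expected <- sum(oracle_k2p_pq(d, kappa))
  se <- stats::sd(frac) / sqrt(n_rep)
  expect_lt(abs(mean(frac) - expected), 3 * se)
  # and the transition share among substitutions follows alpha/(alpha+...)
  set.seed(78)
  big <- mutate_ltr_pair(rdna(2e4), 0.1, kappa)
  pq <- oracle_k2p_pq(0.1, kappa)
  expect_equal(big$transitions / (big$transitions + big$transversions),
               pq[["P"]] / sum(pq), tolerance = 0.05)
})

test_that("planted elements round-trip through the genome sequence", {
  sim <- simulate_genome(small_cfg())
  expect_equal(nrow(sim$elements), 4)             # truth-row conservation
  pairs <- extract_ltr_pairs(sim)
  tab <- date_ltr_pairs(pairs$ltr5, pairs$ltr3, pairs$element_id)
  expect_equal(tab$transitions, sim$elements$realized_transitions)
  expect_equal(tab$transversions, sim$elements$realized_transversions)
  # element intervals respect chromosome bounds and do not overlap
  el <- sim$elements
  expect_true(all(el$start >= 0 & el$end <= sim$config$genome_length))
  for (ch in unique(el$chrom)) {
    e <- el[el$chrom == ch, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})

test_that("oversized element footprints are a configuration error", {
  expect_error(sim_config(genome_length = 1000, ltr_length = 600),
               "footprint")
  expect_error(sim_config(divergence_per_pair = 0.6), "divergence")
  expect_error(mutate_ltr_pair("ACGTX", 0.1), "non-ACGT")
  expect_identical(
    substr(mutate_ltr_pair("ACGTN", 0, iupac = TRUE)$ltr_a, 5, 5), "N")
})

test_that("ecc counts honour the null and the degenerate settings", {
  cfg <- small_cfg(ecc_background = 0, enrichment_factor = 0,
                   off_target_reads = 10)
  truth <- data.frame(element_id = paste0("e", 1:20),
                      enriched = rep(c(TRUE, FALSE), 10))
  zero <- simulate_ecc_counts(cfg, truth, seed = 1)
  expect_true(all(zero$count_plus == 0 & zero$count_minus == 0))

  cfg <- small_cfg(enrichment_factor = 1)
  truth <- data.frame(element_id = sprintf("e%03d", 1:500),
                      enriched = rep(FALSE, 500))
  counts <- simulate_ecc_counts(cfg, truth, seed = 2)
  res <- detect_ecc_elements(counts)
  expect_lte(mean(res$p_value < 0.01), 0.03)  # type-I control
})

test_that("TIP simulation reproduces bias, sharing and support structure", {
  sim <- simulate_genome(small_cfg())
  ann <- compartments_from_truth(sim$centromere_truth, sim$chrom_lengths)

  cfg1 <- small_cfg(n_tips = 120,
                    tip_group_peri_bias = c(g1 = 1, g2 = 1, g3 = 1))
  tips <- simulate_tips(cfg1, ann, seed = 4)
  comp <- classify_compartment(tips$chrom, tips$position, ann)
  expect_true(all(comp %in% c("centromere", "pericentromere")))

  cfg2 <- small_cfg(n_tips = 1000)
  tips <- simulate_tips(cfg2, ann, seed = 5)
  expect_equal(nrow(tips), 1000)                # truth-row conservation
  ss <- sharing_spectrum(tips, n_accessions = 12)
  expect_lt(abs(ss$fraction_le2 - 0.85), 0.03)

  # boundary of the support filter: everything at 5 reads drops out
  tips$support_reads <- 5L
  expect_equal(nrow(filter_tips(tips)), 0)
})

test_that("simulated files are written in standard formats", {
  dir <- withr::local_tempdir()
  sim <- simulate_genome(small_cfg(), out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fa", "elements.gff3", "genes.gff3", "line_hits.bed",
           "elements_truth.tsv", "centromere_truth.tsv")))))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(unname(nchar(as.character(fa))),
               rep(2e5, 2))
  gff <- rtracklayer::import(file.path(dir, "elements.gff3"))
  expect_equal(sum(gff$type == "LTR_retrotransposon"), 4)
  expect_equal(sum(gff$type == "long_terminal_repeat"), 8)

  # byte-identical files under the same config + seed (hash equality)
  dir2 <- withr::local_tempdir()
  simulate_genome(small_cfg(), out_dir = dir2)
  for (f in list.files(dir)) {
    expect_equal(unname(tools::md5sum(file.path(dir, f))),
                 unname(tools::md5sum(file.path(dir2, f))),
                 info = f)
  }
})

test_that("the aORF family plants exactly the configured carrier count", {
  fam <- simulate_aorf_family(n_members = 40, presence_rate = 0.75,
                              seed = 6)
  expect_equal(nrow(fam$truth), 40)
  expect_equal(sum(fam$truth$carrier), 30)
  # reference protein: proline-rich, starts with M, 151 residues
  expect_equal(nchar(fam$reference_protein), 151)
  expect_equal(substr(fam$reference_protein, 1, 1), "M")
  comp <- aa_composition(fam$reference_protein)
  expect_equal(comp$fraction[comp$residue == "P"], 24 / 151)
  # every carrier retains an intact planted ORF
  carriers <- fam$members[fam$truth$carrier]
  orfs <- find_orfs(carriers[[1]], min_length = 300)
  # the planted ORF survives (possibly extended upstream into the flank
  # when a chance in-frame ATG precedes it)
  expect_true(any(orfs$aa_length >= 151 & orfs$strand == "+"))
})
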