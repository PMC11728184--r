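mk_hits <- function(chrom, starts, similarity = 90) {
  data.frame(chrom = chrom, start = starts, end = starts + 100,
             similarity = similarity)
}

test_that("window flagging uses strict >6 hits and >70% similarity", {
  lens <- c(chr1 = 1e6)
  # 6 qualifying hits in window [200000, 300000): not centromeric
  h6 <- mk_hits("chr1", seq(210000, 260000, by = 10000))
  expect_warning(ann <- call_centromeres(h6, lens), "no centromere")
  expect_true(all(ann$compartment == "arm"))

  # a 7th hit flips the window to centromeric
  h7 <- mk_hits("chr1", seq(210000, 270000, by = 10000))
  ann <- call_centromeres(h7, lens)
  cen <- ann[ann$compartment == "centromere", ]
  expect_equal(cen$start, 2e5)
  expect_equal(cen$end, 3e5)

  # similarity at or below 70% never counts
  h65 <- mk_hits("chr1", seq(210000, 290000, by = 5000), similarity = 65)
  expect_warning(ann <- call_centromeres(h65, lens), "no centromere")
  expect_true(all(ann$compartment == "arm"))
  h70 <- mk_hits("chr1", seq(210000, 290000, by = 5000), similarity = 70)
  expect_warning(call_centromeres(h70, lens), "no centromere")
})

test_that("compartments tile the chromosome with a 10% pericentromere", {
  lens <- c(chr1 = 1e6)
  h <- mk_hits("chr1", c(seq(400500, 460500, by = 10000),
                         seq(500500, 560500, by = 10000)))
  ann <- call_centromeres(h, lens)
  # tiling: segments are disjoint, sorted, and sum to the length
  expect_equal(ann$start[1], 0)
  expect_equal(ann$end[nrow(ann)], 1e6)
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)]))
  expect_equal(sum(ann$end - ann$start), 1e6)
  peri <- sum((ann$end - ann$start)[ann$compartment == "pericentromere"])
  expect_equal(peri, 0.10 * 1e6)

  # hit-order invariance
  ann2 <- call_centromeres(h[sample(nrow(h)), ], lens)
  expect_equal(as.data.frame(ann2), as.data.frame(ann))
})

test_that("compartment classification is half-open and boundary-exact", {
  lens <- c(chr1 = 1e6)
  ann <- compartments_from_truth(
    data.frame(chrom = "chr1", start = 4e5, end = 6e5), lens)
  expect_equal(classify_compartment("chr1", 5e5, ann), "centromere")
  expect_equal(classify_compartment("chr1", 0, ann), "arm")
  expect_equal(classify_compartment("chr1", 4e5 - 1, ann),
               "pericentromere")
  expect_equal(classify_compartment("chr1", 4e5, ann), "centromere")
  expect_equal(classify_compartment("chr1", 6e5, ann), "pericentromere")
  expect_equal(classify_compartment("chr1", 6e5 + 5e4, ann), "arm")

  # frequencies of uniform positions track compartment lengths
  set.seed(12)
  pos <- floor(runif(4000, 0, 1e6))
  tab <- table(classify_compartment(rep("chr1", 4000), pos, ann))
  expect_equal(unname(tab[["centromere"]]) / 4000, 0.2, tolerance = 0.1)
  expect_equal(unname(tab[["arm"]]) / 4000, 0.7, tolerance = 0.05)
})

test_that("genic classification respects the +/-2000 bp flank exactly", {
  genes <- data.frame(chrom = "chr1", start = 10000, end = 13000)
  cls <- function(pos) classify_genic("chr1", pos, genes, flank = 2000)
  expect_equal(cls(10000 - 1999), "genic")
  expect_equal(cls(10000 - 2000), "genic")
  expect_equal(cls(10000 - 2001), "intergenic")
  expect_equal(cls(12999 + 2000), "genic")     # last gene base + 2000
  expect_equal(cls(12999 + 2001), "intergenic")
  expect_equal(cls(11500), "genic")            # inside the gene body
  expect_equal(classify_genic("chr2", 11500, genes), "intergenic")
})

test_that("support filtering keeps strictly more than five reads", {
  tips <- data.frame(tip = 1:10,
                     support_reads = c(0, 1, 4, 5, 5, 6, 6, 7, 20, 3))
  kept <- filter_tips(tips)
  expect_equal(nrow(kept), 4)
  expect_true(all(kept$support_reads > 5))
  expect_equal(nrow(filter_tips(tips[0, ])), 0)
})

test_that("sharing spectrum counts accession multiplicities", {
  tips <- data.frame(accessions = c("a1", "a2", "a1,a3", "a1,a2,a4"))
  ss <- sharing_spectrum(tips, n_accessions = 4)
  expect_equal(ss$spectrum$n_tips, c(2, 1, 1, 0))
  expect_equal(ss$fraction_le2, 0.75)
  priv <- sharing_spectrum(data.frame(n_accessions = rep(1, 9)))
  expect_equal(priv$spectrum$fraction[1], 1)
})

test_that("group summaries match the Welch t-test closed form", {
  tips <- rbind(
    data.frame(group = "gA", accessions = rep(c("a1", "a2", "a3"),
                                              times = c(4, 6, 8))),
    data.frame(group = "gB", accessions = rep(c("a1", "a2", "a3"),
                                              times = c(10, 14, 18))))
  gs <- group_summary(tips)
  expect_equal(gs$summary$mean, c(6, 14))
  expect_equal(gs$summary$sd, c(2, 4))
  # Welch: t = (6-14)/sqrt(4/3 + 16/3); df by Welch-Satterthwaite
  t_hand <- (6 - 14) / sqrt(4 / 3 + 16 / 3)
  df_hand <- (4 / 3 + 16 / 3)^2 /
    ((4 / 3)^2 / 2 + (16 / 3)^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(gs$tests$t, t_hand)
  expect_equal(gs$tests$df, df_hand)
  expect_equal(gs$tests$p_value, p_hand)

  # identical groups: t = 0, p = 1, no stars
  same <- rbind(data.frame(group = "gA", accessions = c("a1", "a2")),
                data.frame(group = "gB", accessions = c("a1", "a2")))
  gs <- group_summary(same)
  expect_equal(gs$tests$t, 0)
  expect_equal(gs$tests$p_value, 1)
  expect_equal(gs$tests$stars, "ns")

  expect_error(group_summary(data.frame(group = "gA", accessions = "a1")),
               "two accessions")
})

test_that("called centromeres recover the planted interval", {
  cfg <- sim_config(seed = 17)
  sim_len <- c(chr1 = cfg$genome_length)
  truth <- data.frame(chrom = "chr1", start = 3e6, end = 5e6)
  set.seed(17)
  h <- simulate_centromere_hits(sim_len, truth,
                                density_cen = cfg$hit_density_centromeric,
                                density_arm = cfg$hit_density_arm)
  ann <- call_centromeres(h, sim_len)
  called <- ann[ann$compartment == "centromere", ]
  expect_gte(interval_jaccard(called, truth), 0.85)
})
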