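test_that("two-sided Fisher p matches enumerated examples", {
  # margins 4/4, N = 8: five tables, enumerated by hand
  expect_equal(fisher_two_sided(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_two_sided(5, 95, 5, 95), 1)
  expect_warning(p <- fisher_two_sided(0, 0, 0, 0), "empty")
  expect_equal(p, 1)
  expect_error(fisher_two_sided(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_two_sided(1.5, 1, 1, 1), "non-negative integers")
})

test_that("Fisher p agrees with lchoose enumeration and fisher.test", {
  set.seed(41)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(2, 10, 40), 1))
    p <- fisher_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9, info = paste(cells, collapse = ","))
    ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p, ft, tolerance = 1e-6,
                 info = paste(cells, collapse = ","))
  }
})

test_that("Fisher p is invariant to row swap and monotone toward extremes", {
  set.seed(42)
  for (i in 1:50) {
    cells <- rpois(4, 15)
    expect_equal(
      fisher_two_sided(cells[1], cells[2], cells[3], cells[4]),
      fisher_two_sided(cells[3], cells[4], cells[1], cells[2]))
  }
  # moving a unit from b to a at fixed margins never increases p once
  # a/b already exceeds c/d
  p_prev <- fisher_two_sided(10, 10, 10, 10)
  a <- 10; b <- 10
  while (b > 0) {
    a <- a + 1; b <- b - 1
    # compensate in the other row to keep all margins fixed
    p <- fisher_two_sided(a, b, 20 - a, a)
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
})

test_that("detection applies the p, direction and breadth criteria", {
  counts <- data.frame(
    element_id = c("e_enriched", "e_null", "e_patchy", "e_depleted"),
    count_plus = c(400, 50, 400, 5),
    count_minus = c(20, 50, 20, 100),
    breadth_plus = c(0.95, 0.95, 0.10, 0.95))
  res <- detect_ecc_elements(counts, total_plus = 10000,
                             total_minus = 10000)
  res <- res[match(counts$element_id, res$element_id), ]
  expect_true(res$passed[res$element_id == "e_enriched"])
  expect_false(res$passed[res$element_id == "e_null"])
  # p far below alpha but breadth 0.10 < 0.8: curation rule blocks it
  expect_lt(res$p_value[res$element_id == "e_patchy"], 0.001)
  expect_false(res$passed[res$element_id == "e_patchy"])
  # significant depletion must not pass (direction requirement)
  expect_lt(res$p_value[res$element_id == "e_depleted"], 0.01)
  expect_false(res$passed[res$element_id == "e_depleted"])
})

test_that("detection is invariant to element order and finds a spike", {
  cfg <- sim_config(seed = 9)
  set.seed(9)
  truth <- data.frame(element_id = sprintf("e%03d", 1:100),
                      enriched = c(TRUE, rep(FALSE, 99)))
  counts <- simulate_ecc_counts(cfg, truth)
  res <- detect_ecc_elements(counts)
  expect_true(res$passed[res$element_id == "e001"])
  expect_lte(sum(res$passed), 2)  # at most the spike + rare false call

  shuf <- counts[sample(nrow(counts)), ]
  attr(shuf, "total_plus") <- attr(counts, "total_plus")
  attr(shuf, "total_minus") <- attr(counts, "total_minus")
  res2 <- detect_ecc_elements(shuf)
  expect_equal(res2$element_id, res$element_id)
  expect_equal(res2$p_value, res$p_value)
})

test_that("enrichment ratio reports the computed coverage ratio", {
  expect_equal(enrichment_ratio(92000, 4000), 23)
  expect_equal(enrichment_ratio(7, 7), 1)
  expect_equal(enrichment_ratio(0, 5), 0)
  expect_identical(enrichment_ratio(5, 0), Inf)
  expect_equal(enrichment_ratio(0, 0), 0)
})
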