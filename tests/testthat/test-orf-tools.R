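revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

cassette <- function(n_codons = 99, codon = "GCT") {
  paste0("ATG", paste(rep(codon, n_codons), collapse = ""), "TAA")
}

test_that("a 303-nt ATG..TAA cassette yields exactly one 100-aa ORF", {
  seq <- cassette()
  orfs <- find_orfs(seq, min_length = 300)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, 0)
  expect_equal(orfs$end, 303)
  expect_equal(orfs$nt_length, 303)
  expect_equal(orfs$aa_length, 100)
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$protein, paste(c("M", rep("A", 99)), collapse = ""))
})

test_that("no-ATG sequences yield nothing unless require_atg is off", {
  seq <- paste(rep("GGC", 120), collapse = "")
  expect_equal(nrow(find_orfs(seq, both_strands = FALSE)), 0)
  open <- find_orfs(seq, both_strands = FALSE, require_atg = FALSE,
                    include_partial = TRUE)
  expect_gt(nrow(open), 0)
  expect_true(all(open$partial))
})

test_that("minus-strand ORFs mirror their forward-strand coordinates", {
  pad5 <- rdna(40, seed = 61)
  pad3 <- rdna(25, seed = 62)
  seq <- paste0(pad5, cassette(), pad3)
  fwd <- find_orfs(seq, min_length = 300)
  rev <- find_orfs(revcomp(seq), min_length = 300)
  expect_equal(nrow(fwd), nrow(rev))
  L <- nchar(seq)
  # mirrored coordinate sets, protein content unchanged
  expect_setequal(paste(L - fwd$end, L - fwd$start, fwd$protein),
                  paste(rev$start, rev$end, rev$protein))
  expect_setequal(fwd$protein, rev$protein)
})

test_that("ORFs re-translate from stored coordinates (round trip)", {
  set.seed(63)
  for (i in 1:5) {
    seq <- rdna(900)
    orfs <- find_orfs(seq, min_length = 90, include_partial = TRUE)
    for (k in seq_len(nrow(orfs))) {
      sub <- substr(seq, orfs$start[k] + 1, orfs$end[k])
      if (orfs$strand[k] == "-") sub <- revcomp(sub)
      if (!orfs$partial[k]) sub <- substr(sub, 1, nchar(sub) - 3)
      expect_equal(
        as.character(Biostrings::translate(Biostrings::DNAString(sub))),
        orfs$protein[k])
    }
  }
})

test_that("nested removal keeps outermost same-strand ORFs only", {
  orf <- function(start, end, strand, frame = 0)
    data.frame(start = start, end = end, strand = strand, frame = frame,
               nt_length = end - start, aa_length = (end - start) / 3 - 1,
               partial = FALSE, protein = "M")
  # chain A > B > C, same strand: only A survives
  chain <- rbind(orf(0, 300, "+"), orf(30, 210, "+", 1),
                 orf(60, 120, "+", 2))
  expect_equal(remove_nested_orfs(chain)$start, 0)
  # identical intervals on opposite strands both survive
  opp <- rbind(orf(0, 300, "+"), orf(0, 300, "-"))
  expect_equal(nrow(remove_nested_orfs(opp)), 2)
  # brute-force audit on random sequences: no same-strand containment
  set.seed(64)
  for (i in 1:10) {
    orfs <- remove_nested_orfs(find_orfs(rdna(1200), min_length = 60))
    for (a in seq_len(nrow(orfs))) for (b in seq_len(nrow(orfs))) {
      if (a == b || orfs$strand[a] != orfs$strand[b]) next
      expect_false(orfs$start[a] <= orfs$start[b] &&
                   orfs$end[b] <= orfs$end[a])
    }
  }
})

test_that("aORF survey finds planted carriers and only them", {
  fam <- simulate_aorf_family(n_members = 30, presence_rate = 0.8,
                              flank = 300, seed = 65)
  sv <- survey_aorf(fam$reference_protein, fam$members)
  expect_equal(sv$n_members, 30)
  expect_equal(sv$n_with_aorf, 24)
  expect_equal(sv$fraction, 80)
  expect_equal(sv$hits$carrier, fam$truth$carrier)

  # unreachable thresholds: nothing qualifies
  sv0 <- survey_aorf(fam$reference_protein, fam$members,
                     min_identity = 101, min_coverage = 101)
  expect_equal(sv0$fraction, 0)

  # members that literally contain the reference cassette: 100%
  exact <- c(x1 = paste0(rdna(100, seed = 9), fam$reference_cassette,
                         rdna(100)))
  sv1 <- survey_aorf(fam$reference_protein, exact)
  expect_equal(sv1$fraction, 100)
  expect_equal(sv1$hits$identity, 100)
})

test_that("amino-acid composition normalises over standard residues", {
  comp <- aa_composition("PPPP")
  expect_equal(comp$fraction[comp$residue == "P"], 1)
  comp <- aa_composition("PA")
  expect_equal(comp$fraction[comp$residue %in% c("P", "A")], c(0.5, 0.5))
  set.seed(66)
  prot <- paste(sample(c("A", "R", "P", "G", "X"), 200, TRUE),
                collapse = "")
  comp <- aa_composition(prot)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
  expect_false(is.null(attr(comp, "nonstandard")))
})

test_that("protein identity matrix is symmetric with a 100 diagonal", {
  prots <- c(p1 = "MKLVPQRSTWYACDEFGHIN",
             p2 = "MKLVPQRSTWYACDEFGHIN",
             p3 = "MKLVAQRSTWYACDEFGHIN")
  m <- identity_matrix(prots)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(m["p1", "p2"], 100)
  expect_equal(m["p1", "p3"], 95)     # 1 of 20 residues changed
})
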