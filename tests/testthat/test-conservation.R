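test_that("reference positions map to alignment columns through gaps", {
  aln <- c(ref = "A-CD", other = "ABCD")
  expect_equal(map_position_to_column(aln, "ref", 2), 3L)
  expect_equal(map_position_to_column(aln, "ref", 1:3), c(1L, 3L, 4L))
  # gapless alignment: column equals position
  aln2 <- c(ref = "ACDEF", sp = "ACDEF")
  expect_equal(map_position_to_column(aln2, "ref", 1:5), 1:5)
  expect_error(map_position_to_column(aln, "nope", 1), "not in alignment")
  expect_error(map_position_to_column(aln, "ref", 4), "out of range")
})

test_that("column mapping round-trips on random gapped alignments", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(20:60, 1)
    ref <- strsplit(random_peptide(n), "")[[1]]
    gapped <- character(0)
    for (r in ref) gapped <- c(gapped, if (runif(1) < 0.3) "-", r)
    aln <- c(ref = paste(gapped, collapse = ""),
             sp = paste(sample(gapped), collapse = ""))
    cols <- map_position_to_column(aln, "ref", seq_len(n))
    # inverse map: the column's residue index among non-gaps is the position
    refg <- strsplit(aln[["ref"]], "")[[1]]
    expect_equal(cumsum(refg != "-")[cols], seq_len(n))
    expect_true(all(refg[cols] == ref))
  }
})

test_that("identical families are 100% conserved at every site", {
  aln <- setNames(rep("KDLSLSEASENK", 14), c("ref", paste0("sp", 1:13)))
  sc <- site_conservation(aln, "ref", c(4, 6))
  expect_equal(sc$conservation, c(100L, 100L))
  expect_equal(sc$n_total, c(14L, 14L))
  expect_equal(sc$ref_residue, c("S", "S"))
})

test_that("one substitution among 14 records rounds to 93%", {
  seqs <- rep("ASAEA", 14)
  seqs[5] <- "ATAEA"  # focal S replaced in one species
  aln <- setNames(seqs, c("ref", paste0("sp", 1:13)))
  sc <- site_conservation(aln, "ref", 2)
  expect_equal(sc$n_match, 13L)
  expect_equal(sc$conservation, 93L)
  # conservative substitution does not count: T at an S site is a non-match
  expect_false(sc$matches[[1]][["sp4"]])
})

test_that("k/14 roundings reproduce the table's percent granularity", {
  # k matching species out of 14 for k = 14..3
  got <- vapply(14:3, function(k) {
    seqs <- c(rep("ASA", k), rep("AGA", 14 - k))
    aln <- setNames(seqs, c("ref", paste0("sp", 1:13)))
    site_conservation(aln, "ref", 2)$conservation
  }, integer(1))
  expect_equal(got, c(100L, 93L, 86L, 79L, 71L, 64L, 57L, 50L, 43L, 36L, 29L, 21L))
})

test_that("a gap at the focal column counts as a non-match", {
  aln <- c(ref = "ASA", sp1 = "A-A", sp2 = "ASA")
  sc <- site_conservation(aln, "ref", 2)
  expect_equal(sc$n_match, 2L)
  expect_equal(sc$conservation, 67L)  # 2/3
})

test_that("conservation is invariant to permuting non-reference records", {
  sim <- gen_ortholog_family("KDLSLSEASENKGSSK", n_species = 14, p_sub = 0.2,
                             seed = 4)
  sites <- c(4, 6, 9)
  sc1 <- site_conservation(sim$alignment, "ref", sites)
  perm <- c("ref", sample(setdiff(names(sim$alignment), "ref")))
  sc2 <- site_conservation(sim$alignment[perm], "ref", sites)
  expect_equal(sc1$conservation, sc2$conservation)
  expect_true(all(sc1$conservation >= 0 & sc1$conservation <= 100))
})

test_that("synthetic families recover the planted substitution rate", {
  # per-column retention among 13 non-reference records, estimated over many
  # columns, approaches 1 - p within binomial error
  p <- 0.15
  sim <- gen_ortholog_family(random_peptide(400), n_species = 14, p_sub = p,
                             seed = 77)
  sc <- site_conservation(sim$alignment, "ref", seq_len(400))
  # exclude the reference from the estimate: matches among the 13 others
  retained <- (sc$n_match - 1) / 13
  est <- mean(retained)
  se <- sqrt(p * (1 - p) / (400 * 13))
  expect_lt(abs(est - (1 - p)), 4 * se)
  # and the generator's own truth agrees with the alignment
  truth_rate <- mean(sim$truth$retained[sim$truth$id != "ref"])
  expect_equal(est, truth_rate, tolerance = 1e-12)
})

test_that("alignment coercion validates shape", {
  expect_error(as_alignment(c(a = "AC")), "at least 2")
  expect_error(as_alignment(c(a = "AC", b = "ACD")), "equal gapped length")
  expect_error(as_alignment(c("AC", "AC")), "named")
})
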