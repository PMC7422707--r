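ASARM <- protein_chain("RRDDSSESSDSGSSSESDGD", id = "ASARM",
                       numbering_offset = 489)

test_that("the ASARM region holds 9 serines, exactly 2 in Ser-x-Glu", {
  pos <- chain_positions(ASARM)
  expect_equal(sum(pos$residue == "S"), 9)
  expect_equal(scan_canonical(ASARM), c(493L, 502L))
})

test_that("canonical scan returns nothing without serines and respects chain ends", {
  expect_equal(scan_canonical("GAVLIE"), integer(0))
  expect_equal(scan_canonical("SE"), integer(0))   # n+2 beyond terminus
  expect_equal(scan_canonical("SAE"), 1L)
})

test_that("extended scan propagates through phosphoserines to a fixed point", {
  # S3 matches S-A-E directly; S1 then qualifies through pSer at n+2
  expect_equal(scan_extended("SESAE"), c(1L, 3L))
  expect_equal(scan_extended("GAVLG"), integer(0))
  # seeding with all serines of the C-terminal peptide keeps the direct
  # matches and can only grow the set
  pep <- protein_chain("RRDDSSESSDSGSSSESDGDALGPEQALISEEDLNSAVDHHHHHH",
                       numbering_offset = 489)
  all_s <- chain_positions(pep)$position[
    chain_positions(pep)$residue == "S"]
  ext <- scan_extended(pep, phospho_positions = all_s)
  expect_true(all(scan_canonical(pep) %in% ext))
  expect_gte(length(ext), length(scan_canonical(pep)))
})

test_that("extended scan is monotone in its seed and idempotent at the fixed point", {
  set.seed(23)
  for (i in 1:15) {
    seq <- random_peptide(80)
    chain <- protein_chain(seq)
    s_pos <- which(strsplit(seq, "")[[1]] == "S")
    seed1 <- sample(s_pos, min(2, length(s_pos)))
    seed2 <- union(seed1, sample(seq_len(80), 3))
    e1 <- scan_extended(chain, seed1)
    e2 <- scan_extended(chain, seed2)
    expect_true(all(e1 %in% e2))
    expect_true(all(scan_canonical(chain) %in% e1))
    # feeding the fixed point back as seed changes nothing
    expect_equal(scan_extended(chain, union(seed1, e1)), e1)
  }
})

test_that("Ser-x-Asp scan finds the known minor-motif sites in their peptides", {
  expect_true(239 %in% scan_sxd(protein_chain("GDNDISPFSGDGQPFK",
                                              numbering_offset = 231)))
  expect_equal(scan_sxd(protein_chain("GDNDISPFSGDGQPFK", numbering_offset = 231)),
               239L)
  expect_equal(scan_sxd(protein_chain("RKEGSSDAAESTNYNEIPK", numbering_offset = 366)),
               370L)
  expect_equal(scan_sxd("SASASE"), integer(0))
})

test_that("acidic n+5..n+7 context identifies S56 and S436 in their peptides", {
  expect_equal(scan_acidic_context(protein_chain("KDLSLSEASENK",
                                                 numbering_offset = 53)),
               56L)  # E at n+6 (position 62)
  expect_equal(scan_acidic_context(protein_chain("NEMDSFNGPSHENIITHGR",
                                                 numbering_offset = 432)),
               436L)  # E at n+7 (position 443)
  expect_equal(scan_acidic_context("SSSSSSSSSS"), integer(0))
})

test_that("strict acidic-context options restrict matches", {
  # S-x-Q with all of n+5..n+7 acidic
  seq <- "SAQGGDEE"
  expect_equal(scan_acidic_context(seq, require_q = TRUE, require_all_acidic = TRUE), 1L)
  expect_equal(scan_acidic_context("SAAGGDEE", require_q = TRUE), integer(0))
  expect_equal(scan_acidic_context("SAQGGDAE", require_all_acidic = TRUE), integer(0))
})

test_that("all scanners agree with a position-wise regex oracle on random sequences", {
  set.seed(31)
  for (i in 1:30) {
    seq <- random_peptide(sample(20:200, 1))
    off <- sample(1:100, 1)
    chain <- protein_chain(seq, numbering_offset = off)
    expect_equal(scan_canonical(chain), oracle_motif(seq, "E") + off - 1L)
    expect_equal(scan_sxd(chain), oracle_motif(seq, "D") + off - 1L)
    # acidic window oracle: direct position-by-position check
    res <- strsplit(seq, "")[[1]]
    want <- which(res == "S" &
                    vapply(seq_along(res), function(n) {
                      w <- n + 5:7
                      any(res[w[w <= length(res)]] %in% c("D", "E"))
                    }, logical(1)))
    expect_equal(scan_acidic_context(chain), as.integer(want) + off - 1L)
  }
})

test_that("site annotation table is consistent with the individual scanners", {
  chain <- protein_chain("SAEGSADGSAAAADESGGGGG")
  ann <- annotate_sites(chain)
  expect_equal(ann$position[ann$sxe], scan_canonical(chain))
  expect_equal(ann$position[ann$sxd], scan_sxd(chain))
  expect_equal(ann$position[ann$acidic_n5_n7], scan_acidic_context(chain))
  expect_true(all(ann$residue == "S"))
})

test_that("threonine scanning is opt-in", {
  expect_equal(scan_canonical("TAE"), integer(0))
  expect_equal(scan_canonical("TAE", include_thr = TRUE), 1L)
})
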