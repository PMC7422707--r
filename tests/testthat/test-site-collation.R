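evtab <- read_evidence(mepe_fixture("mepe_lcms_evidence.tsv"))

test_that("collating the packaged evidence yields 22 sites with the printed Ser/Thr split", {
  map <- collate_lcms(evtab)
  expect_equal(nrow(map), 22)
  expect_equal(sum(map$ambiguous), 2)
  tal <- mepephos:::residue_tally(map)
  expect_equal(tal$n_ser_min, 20L)
  expect_equal(tal$n_ser_max, 21L)
  expect_equal(tal$n_thr_min, 1L)
  expect_equal(tal$n_thr_max, 2L)
  # the two either-or pairs are the known ambiguous units
  expect_setequal(map$site[map$ambiguous], c("103|104", "370|371"))
})

test_that("per-site spectral counts aggregate by maximum, not sum", {
  map <- collate_lcms(evtab)
  # 441 appears on two rows (counts 31 and 1); 436 likewise (5 and 1)
  expect_equal(map$spectral_count[map$site == "441"], 31L)
  expect_equal(map$spectral_count[map$site == "436"], 5L)
  expect_equal(map$n_rows[map$site == "441"], 2L)
})

test_that("major-site classification at threshold 20 returns the four high-count sites", {
  map <- collate_lcms(evtab)
  expect_equal(classify_major(map, 20), c(43L, 222L, 362L, 441L))
  flagged <- flag_major_sites(map, 20)
  expect_equal(sum(flagged$major), 4)
  # threshold 1 returns every site's candidates
  expect_length(suppressWarnings(classify_major(map, 1)), 24)
})

test_that("major-site calls are monotone non-increasing in the threshold", {
  map <- collate_lcms(evtab)
  prev <- suppressWarnings(classify_major(map, 1))
  for (th in c(2, 5, 10, 20, 31, 40)) {
    cur <- suppressWarnings(classify_major(map, th))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_length(classify_major(map, 40), 0)
})

test_that("collation totals ignore row order and duplicated rows", {
  map0 <- collate_lcms(evtab)
  shuffled <- evtab[sample(nrow(evtab)), ]
  map1 <- collate_lcms(shuffled)
  expect_equal(nrow(map1), nrow(map0))
  expect_equal(map1$site, map0$site)
  doubled <- rbind(evtab, evtab)
  map2 <- collate_lcms(doubled)
  expect_equal(nrow(map2), nrow(map0))
  expect_equal(map2$spectral_count, map0$spectral_count)
})

test_that("evidence validation rejects inconsistent rows", {
  bad_span <- data.frame(peptide = "SAK", start = 1, end = 5,
                         phospho = "1", counts = 1)
  expect_error(collate_lcms(bad_span), "length disagrees")
  bad_residue <- data.frame(peptide = "GAK", start = 1, end = 3,
                            phospho = "2", counts = 1)
  expect_error(collate_lcms(bad_residue), "not a phospho-acceptor")
  out_of_span <- data.frame(peptide = "SAK", start = 10, end = 12,
                            phospho = "2", counts = 1)
  expect_error(collate_lcms(out_of_span), "outside peptide span")
  # with a parent chain, mismatching rows are dropped with a warning
  parent <- protein_chain("SAKGTEK", id = "p")
  rows <- data.frame(peptide = c("SAK", "GTEK"), start = c(1, 4), end = c(3, 7),
                     phospho = c("1", "5"), counts = c(2, 3))
  rows$peptide[2] <- "GTEG"  # disagrees with parent
  expect_warning(map <- collate_lcms(rows, parent = parent), "dropping 1")
  expect_equal(nrow(map), 1)
})

test_that("empty evidence collates to an empty map with zero totals", {
  map <- collate_lcms(evtab[0, ])
  expect_equal(nrow(map), 0)
  tot <- site_totals(map)
  expect_equal(tot$grand_total, 0L)
  expect_equal(tot$n_lcms, 0L)
})

test_that("a full MALDI ladder marks all region serines as assumed sites", {
  map <- collate_lcms(evtab)
  asarm_serines <- c(493L, 494L, 496L, 497L, 499L, 501L, 502L, 503L, 505L)
  merged <- merge_maldi(map, asarm_serines, ladder_max = 10, tag_phospho = 1)
  expect_equal(nrow(merged), 31)
  expect_equal(sum(merged$source == "MALDI"), 9)
  expect_true(all(merged$status[merged$source == "MALDI"] == "assumed (region-level)"))
  tot <- site_totals(merged)
  expect_equal(tot$grand_total, 31L)
  expect_equal(tot$n_lcms, 22L)
  expect_equal(tot$n_maldi_region, 9L)
  expect_equal(tot$n_tag_phospho, 1L)
})

test_that("an insufficient ladder leaves the site map unchanged", {
  map <- collate_lcms(evtab)
  asarm_serines <- c(493L, 494L, 496L, 497L, 499L, 501L, 502L, 503L, 505L)
  same <- merge_maldi(map, asarm_serines, ladder_max = 0, tag_phospho = 0)
  expect_equal(nrow(same), 22)
  expect_match(attr(same, "maldi_note"), "no site-level assignment")
  # 9 phosphates minus 1 tag reservation cannot cover 9 serines either
  partial <- merge_maldi(map, asarm_serines, ladder_max = 9, tag_phospho = 1)
  expect_equal(nrow(partial), 22)
})

test_that("synthetic evidence with known truth collates back to the truth", {
  sim_chain <- gen_protein(200, n_sxe = 4, n_sxd = 2, seed = 5)$chain
  for (seed in 1:5) {
    sim <- gen_evidence_table(sim_chain, n_sites = 8, ambiguity_rate = 0,
                              seed = seed)
    map <- collate_lcms(sim$evidence, parent = sim_chain)
    expect_equal(map$position, sim$truth$position)
    expect_false(any(map$ambiguous))
    # sites given counts >= threshold are exactly those classified major
    th <- 10L
    expect_equal(classify_major(map, th), sort(sim$truth$position[sim$truth$counts >= th]))
  }
})

test_that("tidy and glance expose per-residue rows and headline totals", {
  map <- flag_major_sites(collate_lcms(evtab), 20)
  td <- tidy(map)
  expect_equal(nrow(td), 24)  # 20 resolved + 2x2 ambiguous candidates
  expect_equal(sum(is.na(td$ambiguity_group)), 20)
  g <- glance(map)
  expect_equal(g$n_lcms, 22L)
  expect_equal(g$n_major, 4L)
})
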