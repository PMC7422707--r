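#' Reproduce the full phosphosite-mapping analysis from packaged fixtures
#'
#' Runs the pipeline end to end on in-repo fixtures: assembles the mutant
#' (K509A/K515A) C-terminal construct, digests it, computes the theoretical
#' average MH+ of the C-terminal tryptic 45-mer, assigns the MALDI
#' phospho-ladder and the phosphatase control, collates the LC-MS/MS
#' phosphopeptide evidence into a residue-level site map, classifies major
#' sites by spectral count, scans the ASARM region for canonical motifs, and
#' merges the region-level MALDI result to obtain the grand total of
#' phosphorylatable residues. Every headline number is recomputed and
#' compared with its expected value, giving a deterministic pass/fail report.
#'
#' @param fixture_dir Directory holding the fixtures (default: the packaged
#'   set). Expected files: `mepe_construct.yml`, `mepe_lcms_evidence.tsv`,
#'   `maldi_asarm_peaks.tsv`, `maldi_asarm_alp_peaks.tsv`.
#' @param major_threshold Spectral-count threshold for major sites
#'   (default 20).
#' @param tolerance Relative ladder-match tolerance (default 0.001 = 0.1%).
#' @param tag_phospho Ladder phosphates attributed to tag serines
#'   (default 1, the observed myc-tag phosphosite).
#' @return A `repro_report`: list with `checks` (tibble of recomputed vs
#'   expected values), `site_map`, `assignments`, `control`, `construct`,
#'   `cterm_peptide`, `major_sites`.
#' @examples
#' \donttest{
#' report <- reproduce()
#' report$checks
#' }
#' @export
reproduce <- function(fixture_dir = mepe_fixture(),
                      major_threshold = 20L,
                      tolerance = 0.001,
                      tag_phospho = 1L) {
  need <- c("mepe_construct.yml", "mepe_lcms_evidence.tsv",
            "maldi_asarm_peaks.tsv", "maldi_asarm_alp_peaks.tsv")
  paths <- file.path(fixture_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing fixture file(s): ", paste(missing, collapse = ", ")))
  }

  cons <- read_construct(paths[1])
  regions <- attr(cons, "regions")
  asarm <- regions[regions$name == "ASARM", ]
  chain <- assemble_construct(cons)

  # C-terminal tryptic peptide: the digestion product starting at the ASARM's
  # leading arginine and running to the construct terminus (2 missed
  # cleavages from the Arg-Arg start under trypsin specificity).
  digest <- trypsin_digest(chain, max_missed = 2L)
  cterm <- filter(digest, .data$start == asarm$start,
                  .data$end == max(digest$end))
  if (nrow(cterm) != 1) abort("C-terminal tryptic peptide not found in digest")
  cterm_seq <- cterm$sequence
  mh <- peptide_mass(cterm_seq, type = "average", charge = "MH+")

  peaks <- read_peaklist(paths[3])
  assignments <- assign_phospho_ladder(peaks, base_mass = mh,
                                       tolerance = tolerance)
  ladder_max <- max_phospho(assignments)
  control <- dephospho_control(peaks, read_peaklist(paths[4]), mh,
                               tolerance = tolerance)

  evidence <- read_evidence(paths[2])
  map <- collate_lcms(evidence)
  map <- flag_major_sites(map, major_threshold)
  major <- classify_major(map, major_threshold)

  asarm_seq <- extract_region(chain, asarm$start, asarm$end)
  asarm_chain <- protein_chain(asarm_seq, id = "ASARM",
                               numbering_offset = asarm$start)
  asarm_serines <- filter(chain_positions(asarm_chain), .data$residue == "S")$position
  asarm_sxe <- scan_canonical(asarm_chain)
  cterm_serines <- stringr::str_count(cterm_seq, "S")

  merged <- merge_maldi(map, asarm_serines, ladder_max, tag_phospho = tag_phospho)
  totals <- site_totals(merged)
  tallies <- residue_tally(map)

  checks <- tibble(
    check = c("cterm_mass_mh_avg", "ladder_max_phospho", "dephospho_control",
              "lcms_sites", "ser_sites_min", "ser_sites_max",
              "thr_sites_min", "thr_sites_max", "major_sites",
              "asarm_serines", "asarm_sxe", "cterm_serines", "grand_total"),
    value = c(round(mh, 1), ladder_max, as.integer(control$pass),
              nrow(map), tallies$n_ser_min, tallies$n_ser_max,
              tallies$n_thr_min, tallies$n_thr_max, length(major),
              length(asarm_serines), length(asarm_sxe), cterm_serines,
              totals$grand_total),
    expected = c(4838.8, 10, 1, 22, 20, 21, 1, 2, 4, 9, 2, 11, 31),
    tolerance = c(0.5, rep(0, 12))
  )
  checks <- mutate(checks, pass = abs(.data$value - .data$expected) <= .data$tolerance)

  structure(
    list(checks = checks, site_map = merged, assignments = assignments,
         control = control, construct = cons, cterm_peptide = cterm_seq,
         cterm_mass = mh, major_sites = major, totals = totals),
    class = "repro_report"
  )
}

#' @export
print.repro_report <- function(x, ...) {
  cat("<repro_report> phosphosite-mapping reproduction\n")
  cat(sprintf("  C-terminal peptide: %s (%d aa)\n",
              paste0(substr(x$cterm_peptide, 1, 20), "..."),
              nchar(x$cterm_peptide)))
  cat(sprintf("  average MH+ %.1f Da; ladder max %d phosphates\n",
              x$cterm_mass, max_phospho(x$assignments)))
  cat(sprintf("  LC-MS/MS sites %d; major sites: %s\n",
              x$totals$n_lcms, paste(x$major_sites, collapse = ", ")))
  cat(sprintf("  grand total %d phosphorylatable residues (+%d tag)\n",
              x$totals$grand_total, x$totals$n_tag_phospho))
  status <- if (all(x$checks$pass)) "PASS" else "FAIL"
  cat(sprintf("  checks: %d/%d pass -> %s\n",
              sum(x$checks$pass), nrow(x$checks), status))
  invisible(x)
}
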