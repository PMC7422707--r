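# Standard residue (monomer) masses in Da. Monoisotopic values from the
# IUPAC 1997 atomic masses; average values from the 2005 standard atomic
# weights. Water and proton terms are added per peptide, not per residue.
RESIDUE_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
MASS_WATER <- c(monoisotopic = 18.0105646, average = 18.01528)
MASS_PROTON <- 1.00727646

# Phosphate increment used for ladder arithmetic and phospho modification.
PHOSPHO_DELTA <- c(monoisotopic = 79.96633, average = 79.9799)

#' Residue and modification mass tables
#'
#' `amino_acid_masses()` returns the per-residue monomer masses used by
#' [peptide_mass()]; `modification_masses()` returns the supported variable
#' and fixed modifications (phosphorylation of S/T/Y, oxidation of Met,
#' carbamidomethylation of Cys — the modification set of the modelled MS
#' search).
#'
#' @return A tibble of masses in Da.
#' @export
amino_acid_masses <- function() {
  tibble(
    residue = names(RESIDUE_MASS_MONO),
    monoisotopic = unname(RESIDUE_MASS_MONO),
    average = unname(RESIDUE_MASS_AVG)
  )
}

#' @rdname amino_acid_masses
#' @export
modification_masses <- function() {
  tibble(
    name = c("phospho", "oxidation", "carbamidomethyl"),
    delta_monoisotopic = c(79.96633, 15.99491, 57.02146),
    delta_average = c(79.9799, 15.9994, 57.0513),
    targets = c("STY", "M", "C")
  )
}

mod_lookup <- function(name, type) {
  tab <- modification_masses()
  i <- match(name, tab$name)
  if (anyNA(i)) abort(paste0("unknown modification(s): ",
                             paste(unique(name[is.na(i)]), collapse = ", ")))
  list(
    delta = if (type == "monoisotopic") tab$delta_monoisotopic[i] else tab$delta_average[i],
    targets = tab$targets[i]
  )
}

#' Theoretical peptide mass
#'
#' Sums residue monomer masses plus one water, plus any modification deltas,
#' plus one proton for the singly protonated MH+ species observed in
#' linear-mode MALDI. Average masses are the default for MALDI comparisons
#' of ~5 kDa peptides (the printed 4838.8 Da for the mutant C-terminal
#' 45-mer is an average MH+); monoisotopic masses are available for
#' high-resolution work.
#'
#' @param x A `protein_chain`, peptide string, or digestion-table sequence.
#' @param modifications `NULL`, or a data frame with columns `name`
#'   (matching [modification_masses()]) and `position` (1-based within the
#'   peptide; `NA` allowed for composition-only bookkeeping of a known
#'   modification count).
#' @param type `"average"` (default) or `"monoisotopic"`.
#' @param charge `"MH+"` (default; singly protonated) or `"M"` (neutral).
#' @return Mass in Da (double scalar).
#' @examples
#' peptide_mass("RRDDSSESSDSGSSSESDGDALGPEQALISEEDLNSAVDHHHHHH")
#' @export
peptide_mass <- function(x, modifications = NULL,
                         type = c("average", "monoisotopic"),
                         charge = c("MH+", "M")) {
  type <- match.arg(type)
  charge <- match.arg(charge)
  seq <- as_residues(x)
  res <- strsplit(seq, "")[[1]]
  tab <- if (type == "monoisotopic") RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  if (any(!res %in% names(tab))) {
    abort(paste0("non-canonical residue(s): ",
                 paste(setdiff(unique(res), names(tab)), collapse = ", ")))
  }
  m <- sum(tab[res]) + MASS_WATER[[type]]
  if (!is.null(modifications) && nrow(modifications) > 0) {
    mods <- as_tibble(modifications)
    stopifnot("name" %in% names(mods))
    if (!"position" %in% names(mods)) mods$position <- NA_integer_
    info <- mod_lookup(mods$name, type)
    ok_pos <- is.na(mods$position)
    if (!all(ok_pos)) {
      pos <- mods$position[!ok_pos]
      if (any(pos < 1 | pos > length(res))) {
        abort("modification position outside peptide")
      }
      target_ok <- stringr::str_detect(
        info$targets[!ok_pos],
        stringr::fixed(res[pos])
      )
      if (!all(target_ok)) {
        abort(sprintf(
          "modification '%s' not allowed on residue %s at position %d",
          mods$name[!ok_pos][!target_ok][1],
          res[pos][!target_ok][1],
          pos[!target_ok][1]
        ))
      }
    }
    m <- m + sum(info$delta)
  }
  if (charge == "MH+") m <- m + MASS_PROTON
  unname(m)
}

#' Theoretical phospho-ladder masses
#'
#' The MALDI signature of progressive phosphorylation is a ladder of peaks
#' spaced by one phosphate (HPO3): 79.9663 Da monoisotopic, 79.98 Da
#' average — the "approximately 80 Da" increments of the intact-peptide
#' spectra.
#'
#' @param base_mass Mass of the unmodified species (same charge convention
#'   as the peaks it will be compared to, typically MH+).
#' @param n_max Highest phosphate count on the ladder.
#' @param type `"average"` (default) or `"monoisotopic"`.
#' @return A tibble with columns `n_phospho` (0..`n_max`) and `mass`.
#' @examples
#' phospho_ladder(4838.8, 10)
#' @export
phospho_ladder <- function(base_mass, n_max, type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  stopifnot(n_max >= 0, base_mass > 0)
  k <- 0:n_max
  tibble(n_phospho = k, mass = base_mass + k * PHOSPHO_DELTA[[type]])
}

#' @rdname phospho_ladder
#' @export
phospho_delta <- function(type = c("average", "monoisotopic")) {
  unname(PHOSPHO_DELTA[[match.arg(type)]])
}
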