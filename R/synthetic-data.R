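# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes: proteins with planted motifs, aligned ortholog
# families with per-column substitution, MALDI ladders with mass noise, and
# phosphopeptide evidence tables with overdispersed spectral counts.

#' Generate a protein chain with planted motifs
#'
#' The background sequence is drawn from an alphabet without serine, so the
#' planted Ser-x-Glu / Ser-x-Asp occurrences are provably the only motif
#' matches (collision-free by construction). Plants occupy disjoint 3-residue
#' windows at random positions.
#'
#' @param length Chain length (>= 10).
#' @param n_sxe,n_sxd Number of planted Ser-x-Glu and Ser-x-Asp motifs.
#' @param seed Integer seed; fixes the chain exactly.
#' @param id Chain id.
#' @return A list with `chain` (`protein_chain`) and `truth` (tibble of
#'   planted motif positions and classes).
#' @export
gen_protein <- function(length, n_sxe = 0L, n_sxd = 0L, seed = 1L,
                        id = "synthetic_protein") {
  stopifnot(length >= 10)
  n_plant <- n_sxe + n_sxd
  if (3L * n_plant > length) abort("too many planted motifs for chain length")
  withr::with_seed(seed, {
    background <- setdiff(AA_ALPHABET, "S")
    res <- sample(background, length, replace = TRUE)
    # non-overlapping 3-residue windows for the plants
    starts <- integer(0)
    free <- seq_len(length - 2L)
    for (i in seq_len(n_plant)) {
      if (length(free) == 0) abort("could not place all planted motifs")
      s <- sample(free, 1L)
      starts <- c(starts, s)
      free <- setdiff(free, (s - 2L):(s + 2L))
    }
    classes <- rep(c("SxE", "SxD"), c(n_sxe, n_sxd))
    x_choices <- setdiff(background, c("E", "D"))  # keep the x neutral
    for (i in seq_along(starts)) {
      res[starts[i]] <- "S"
      res[starts[i] + 1L] <- sample(x_choices, 1L)
      res[starts[i] + 2L] <- if (classes[i] == "SxE") "E" else "D"
    }
  })
  chain <- protein_chain(paste(res, collapse = ""), id = id)
  truth <- tibble(position = starts, motif = classes)
  truth <- arrange(truth, .data$position)
  list(chain = chain, truth = truth)
}

#' Generate an aligned ortholog family by per-column substitution
#'
#' Each non-reference record substitutes every column independently with
#' probability `p_sub` (to a uniformly chosen different residue). There is
#' no phylogeny and no indel process: the generator exercises the
#' conservation arithmetic, not sequence evolution.
#'
#' @param reference A `protein_chain` or residue string.
#' @param n_species Family size including the reference (default 14, the
#'   study's mammalian panel size).
#' @param p_sub Per-column substitution probability.
#' @param seed Integer seed.
#' @param forced_mismatches Optional tibble with `id`, `position` forcing a
#'   substitution at a reference position in a named record (used to plant
#'   exact conservation fractions).
#' @return A list with `alignment` (named character vector, reference first,
#'   named `"ref"`) and `truth` (tibble: per record and reference position,
#'   whether the reference residue is retained).
#' @export
gen_ortholog_family <- function(reference, n_species = 14L, p_sub = 0.1,
                                seed = 1L, forced_mismatches = NULL) {
  stopifnot(n_species >= 2, p_sub >= 0, p_sub <= 1)
  ref <- strsplit(as_residues(reference), "")[[1]]
  n <- length(ref)
  ids <- c("ref", paste0("sp", seq_len(n_species - 1L)))
  recs <- withr::with_seed(seed, {
    lapply(seq_len(n_species - 1L), function(i) {
      s <- ref
      flip <- runif(n) < p_sub
      if (any(flip)) {
        s[flip] <- vapply(s[flip], function(r) sample(setdiff(AA_ALPHABET, r), 1L),
                          character(1))
      }
      s
    })
  })
  names(recs) <- ids[-1]
  if (!is.null(forced_mismatches)) {
    fm <- as_tibble(forced_mismatches)
    for (i in seq_len(nrow(fm))) {
      rec <- fm$id[i]; pos <- as.integer(fm$position[i])
      if (!rec %in% names(recs)) abort(sprintf("unknown record '%s'", rec))
      recs[[rec]][pos] <- setdiff(AA_ALPHABET, ref[pos])[1]
    }
  }
  aln <- c(ref = paste(ref, collapse = ""),
           vapply(recs, paste, character(1), collapse = ""))
  truth <- purrr::map_dfr(names(aln), function(id) {
    s <- strsplit(aln[[id]], "")[[1]]
    tibble(id = id, position = seq_len(n), retained = s == ref)
  })
  list(alignment = aln, truth = truth)
}

#' Generate a MALDI phospho-ladder peak list with noise
#'
#' Rung peaks sit at `base + k * delta` plus Gaussian mass noise; spurious
#' peaks are added uniformly over the observed m/z window at a Poisson rate.
#'
#' @param base_mass Unmodified MH+ mass.
#' @param ks Integer phosphate counts present (e.g. `0:10`).
#' @param sigma Mass noise standard deviation in Da.
#' @param noise_rate Expected number of spurious peaks (Poisson mean).
#' @param seed Integer seed.
#' @param type Mass scale of the increment (default average).
#' @return A list with `peaks` (tibble `mz`, `intensity`) and `truth`
#'   (tibble `mz`, `n_phospho`; `NA` for noise peaks).
#' @export
gen_peaklist <- function(base_mass, ks = 0:10, sigma = 0.3, noise_rate = 0,
                         seed = 1L, type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  stopifnot(sigma >= 0, noise_rate >= 0, base_mass > 0)
  delta <- phospho_delta(type)
  withr::with_seed(seed, {
    rungs <- base_mass + ks * delta + rnorm(length(ks), 0, sigma)
    n_noise <- rpois(1, noise_rate)
    k_top <- if (length(ks) > 0) max(ks) else 10L
    lo <- base_mass - 0.5 * delta
    hi <- base_mass + (k_top + 0.5) * delta
    noise <- runif(n_noise, lo, hi)
    intensity <- c(runif(length(ks), 10, 100), runif(n_noise, 1, 10))
  })
  truth <- tibble(mz = c(rungs, noise),
                  n_phospho = c(as.integer(ks), rep(NA_integer_, length(noise))))
  ord <- order(truth$mz)
  list(
    peaks = tibble(mz = truth$mz[ord], intensity = intensity[ord]),
    truth = truth[ord, ]
  )
}

#' Generate a phosphopeptide evidence table with known truth
#'
#' True sites are drawn from the chain's Ser/Thr positions; each site is
#' reported on a tryptic peptide of the chain that covers it (0--2 missed
#' cleavages), with spectral counts drawn from a negative binomial
#' (overdispersed, mimicking the long-tailed counts of real tables) and a
#' configurable fraction of sites turned into adjacent-acceptor either-or
#' pairs.
#'
#' @param chain A `protein_chain`.
#' @param n_sites Number of true phosphosites.
#' @param count_mean,count_dispersion Negative-binomial mean and size.
#' @param ambiguity_rate Probability that a site is reported as an ambiguous
#'   pair with the nearest other Ser/Thr in the same peptide (skipped when no
#'   partner exists).
#' @param seed Integer seed.
#' @return A list with `evidence` (tibble for [collate_lcms()]) and `truth`
#'   (tibble: `position`, `partner` (`NA` when resolved), `counts`).
#' @export
gen_evidence_table <- function(chain, n_sites, count_mean = 6, count_dispersion = 0.6,
                               ambiguity_rate = 0, seed = 1L) {
  stopifnot(ambiguity_rate >= 0, ambiguity_rate <= 1)
  pos_tab <- filter(chain_positions(chain), .data$residue %in% c("S", "T"))
  if (n_sites > nrow(pos_tab)) abort("not enough Ser/Thr acceptors in chain")
  if (n_sites == 0) {
    empty_ev <- tibble(peptide = character(), start = integer(), end = integer(),
                       phospho = character(), counts = integer())
    return(list(evidence = empty_ev,
                truth = tibble(position = integer(), partner = integer(),
                               counts = integer())))
  }
  peptides <- trypsin_digest(chain, max_missed = 2L)
  withr::with_seed(seed, {
    sites <- sort(sample(pos_tab$position, n_sites))
    counts <- pmax(1L, rnbinom(n_sites, mu = count_mean, size = count_dispersion))
    ambig <- runif(n_sites) < ambiguity_rate
    rows <- purrr::map_dfr(seq_along(sites), function(i) {
      s <- sites[i]
      cover <- filter(peptides, .data$start <= s, .data$end >= s)
      # prefer MS-plausible peptide lengths when available
      roomy <- filter(cover, nchar(.data$sequence) >= 6)
      if (nrow(roomy) > 0) cover <- roomy
      pep <- cover[sample(nrow(cover), 1L), ]
      partner <- NA_integer_
      if (ambig[i]) {
        others <- setdiff(
          filter(pos_tab, .data$position >= pep$start,
                 .data$position <= pep$end)$position,
          sites)
        if (length(others) > 0) partner <- others[which.min(abs(others - s))]
      }
      phospho <- if (is.na(partner)) as.character(s) else site_key(c(s, partner))
      tibble(peptide = pep$sequence, start = pep$start, end = pep$end,
             phospho = phospho, counts = counts[i],
             true_position = s, partner = partner)
    })
  })
  list(
    evidence = select(rows, "peptide", "start", "end", "phospho", "counts"),
    truth = select(rows, position = "true_position", "partner", "counts")
  )
}
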