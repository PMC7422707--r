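#' Protease cleavage rules
#'
#' Cleavage happens C-terminal to any residue in `cut_after` unless the next
#' residue is in `blocked_by_next`. The default is trypsin specificity: cut
#' after Lys/Arg, blocked by a following Pro.
#'
#' @param cut_after Residues after which the backbone is cut.
#' @param blocked_by_next Residues that block cleavage when immediately
#'   C-terminal to the cut site.
#' @return A `cleavage_rule` object.
#' @export
cleavage_rule <- function(cut_after = c("K", "R"), blocked_by_next = "P") {
  cut_after <- toupper(cut_after)
  blocked_by_next <- toupper(blocked_by_next)
  stopifnot(length(cut_after) >= 1)
  structure(list(cut_after = cut_after, blocked_by_next = blocked_by_next),
            class = "cleavage_rule")
}

#' Cleavage sites of a chain under a rule
#'
#' @param chain A `protein_chain` or residue string.
#' @param rule A `cleavage_rule`; default trypsin.
#' @return Integer vector of printed positions of the residues after which
#'   cleavage occurs (the chain terminus is not a site).
#' @export
cleavage_sites <- function(chain, rule = cleavage_rule()) {
  res <- strsplit(as_residues(chain), "")[[1]]
  n <- length(res)
  if (n < 2) return(integer())
  idx <- which(res[-n] %in% rule$cut_after & !(res[-1] %in% rule$blocked_by_next))
  chain_offset(chain) + idx - 1L
}

#' In-silico proteolytic digestion
#'
#' Enumerates every peptide carrying 0 to `max_missed` internal missed
#' cleavages, with printed-position coordinates inherited from the chain.
#' The MS search settings modelled here use trypsin with at most two missed
#' cleavages, which is why e.g. the mutant C-terminal 45-mer (preceded by
#' the Arg489-Arg490 pair) is a legitimate product: its two leading arginines
#' contribute two internal missed cleavages.
#'
#' @param chain A `protein_chain` or residue string.
#' @param max_missed Maximum number of internal missed cleavages (default 2,
#'   the modelled search setting).
#' @param rule A `cleavage_rule`; default trypsin.
#' @return A tibble with columns `parent_id`, `start`, `end` (printed
#'   positions), `sequence`, `missed_cleavages`, ordered by `start` then
#'   peptide length.
#' @examples
#' trypsin_digest(protein_chain("RRDDSSESSDSGK"), max_missed = 2)
#' @export
trypsin_digest <- function(chain, max_missed = 2L, rule = cleavage_rule()) {
  stopifnot(max_missed >= 0)
  seq <- as_residues(chain)
  off <- chain_offset(chain)
  id <- if (inherits(chain, "protein_chain")) chain$id else "chain"
  n <- nchar(seq)
  if (n == 0) {
    return(tibble(parent_id = character(), start = integer(), end = integer(),
                  sequence = character(), missed_cleavages = integer()))
  }
  sites_idx <- cleavage_sites(chain, rule) - off + 1L
  bounds <- c(0L, sites_idx, n)          # interval i spans (bounds[i], bounds[i+1]]
  k <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (m in 0:min(max_missed, k - 1L)) {
    first <- seq_len(k - m)
    starts <- bounds[first] + 1L
    ends <- bounds[first + m + 1L]
    out[[length(out) + 1L]] <- tibble(
      parent_id = id,
      start = off + starts - 1L,
      end = off + ends - 1L,
      sequence = substring(seq, starts, ends),
      missed_cleavages = m
    )
  }
  arrange(bind_rows(out), .data$start, .data$end)
}

#' Compare cleavage sites of two constructs or chains
#'
#' Reports the cleavage sites lost and gained between a wild-type and a
#' mutant sequence — e.g. the K509A/K515A substitutions remove the two
#' tryptic sites that otherwise split the C-terminal ASARM peptide from the
#' myc tag, which is what makes the 45-mer observable by MALDI.
#'
#' @param wt,mut `construct` or `protein_chain` objects of equal length.
#' @param rule A `cleavage_rule`; default trypsin.
#' @return A tibble with columns `position`, `change` (`"lost"` sites present
#'   only in `wt`, `"gained"` only in `mut`), `wt_residue`, `mut_residue`.
#' @export
explain_mutation_effect <- function(wt, mut, rule = cleavage_rule()) {
  if (inherits(wt, "construct")) wt <- assemble_construct(wt)
  if (inherits(mut, "construct")) mut <- assemble_construct(mut)
  if (chain_length(wt) != chain_length(mut)) {
    abort("wild-type and mutant chains must have equal length")
  }
  s_wt <- cleavage_sites(wt, rule)
  s_mut <- cleavage_sites(mut, rule)
  pos <- sort(c(setdiff(s_wt, s_mut), setdiff(s_mut, s_wt)))
  if (length(pos) == 0) {
    return(tibble(position = integer(), change = character(),
                  wt_residue = character(), mut_residue = character()))
  }
  tibble(
    position = pos,
    change = if_else(pos %in% s_wt, "lost", "gained"),
    wt_residue = residue_at(wt, pos),
    mut_residue = residue_at(mut, pos)
  )
}
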