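scan_positions <- function(chain, target = "S", include_thr = FALSE) {
  res <- strsplit(as_residues(chain), "")[[1]]
  targets <- if (include_thr) c("S", "T") else "S"
  which(res %in% targets)
}

#' Scan for the canonical FAM20C motif Ser-x-Glu
#'
#' A position n matches when it holds Ser (optionally also Thr with
#' `include_thr = TRUE`) and position n+2 holds Glu. Matches may overlap;
#' window positions beyond the chain terminus cannot match (no padding).
#' Returned positions use the chain's printed numbering.
#'
#' @param chain A `protein_chain` or residue string.
#' @param include_thr Also scan threonine (default `FALSE`: the motif
#'   analysis in this system is serine-centred).
#' @return Sorted integer vector of printed positions.
#' @examples
#' scan_canonical(protein_chain("RRDDSSESSDSGSSSESDGD", numbering_offset = 489))
#' @export
scan_canonical <- function(chain, include_thr = FALSE) {
  res <- strsplit(as_residues(chain), "")[[1]]
  idx <- scan_positions(chain, include_thr = include_thr)
  idx <- idx[idx + 2 <= length(res) & res[idx + 2] == "E"]
  chain_offset(chain) + idx - 1L
}

#' Scan for Ser-x-Glu/pSer with fixed-point propagation
#'
#' FAM20C's full consensus accepts a phosphoserine in place of the Glu:
#' once a serine at n+2 is phosphorylated, the serine at n becomes a
#' substrate. Starting from the direct Ser-x-Glu matches plus any supplied
#' phosphosites, serines whose n+2 position is in the set are added until a
#' fixed point is reached (the set is monotone and bounded, so this
#' terminates).
#'
#' @param chain A `protein_chain` or residue string.
#' @param phospho_positions Known/assumed phosphosite positions (printed
#'   numbering) used to seed propagation; default none.
#' @param include_thr Also treat threonine as a substrate (default `FALSE`).
#' @return Sorted integer vector of printed positions of motif-conforming
#'   serines (the direct Ser-x-Glu matches plus all propagated Ser-x-pSer
#'   matches; seed positions that are not themselves motif hits are not
#'   returned).
#' @examples
#' scan_extended("SESAE")   # S3 via S-A-E, then S1 via S-E-pS3
#' @export
scan_extended <- function(chain, phospho_positions = integer(),
                          include_thr = FALSE) {
  res <- strsplit(as_residues(chain), "")[[1]]
  off <- chain_offset(chain)
  n <- length(res)
  bad <- phospho_positions[phospho_positions < off | phospho_positions > off + n - 1L]
  if (length(bad) > 0) abort("phospho position(s) outside chain")
  cand <- scan_positions(chain, include_thr = include_thr)   # chain-local indices
  seed_local <- as.integer(phospho_positions) - off + 1L
  direct <- cand[cand + 2 <= n & res[cand + 2] == "E"]
  active <- sort(unique(c(direct, seed_local)))
  hits <- direct
  repeat {
    new <- cand[(cand + 2) %in% active & !(cand %in% hits)]
    if (length(new) == 0) break
    hits <- c(hits, new)
    active <- sort(unique(c(active, new)))
  }
  sort(off + hits - 1L)
}

#' Scan for the Ser-x-Asp motif
#'
#' Ser-x-Asp is a secondary acceptor motif of secreted-protein kinases
#' (phosphorylated on the related SIBLING protein osteopontin): position n
#' holds Ser, position n+2 holds Asp.
#'
#' @inheritParams scan_canonical
#' @return Sorted integer vector of printed positions.
#' @export
scan_sxd <- function(chain, include_thr = FALSE) {
  res <- strsplit(as_residues(chain), "")[[1]]
  idx <- scan_positions(chain, include_thr = include_thr)
  idx <- idx[idx + 2 <= length(res) & res[idx + 2] == "D"]
  chain_offset(chain) + idx - 1L
}

#' Scan for serines with acidic context at n+5..n+7
#'
#' Generalization of the SxQxxDEE-type motif in which acidic residues five
#' to seven positions downstream are the critical determinants. The default
#' (lenient) rule requires at least one Asp/Glu anywhere in n+5..n+7;
#' strictness can be raised to require Gln at n+2 and/or all three window
#' positions acidic.
#'
#' @inheritParams scan_canonical
#' @param require_q Require Gln at n+2 (literal SxQ...; default `FALSE`).
#' @param require_all_acidic Require every residue at n+5..n+7 to be
#'   Asp/Glu (default `FALSE`: at least one suffices).
#' @return Sorted integer vector of printed positions.
#' @export
scan_acidic_context <- function(chain, include_thr = FALSE,
                                require_q = FALSE, require_all_acidic = FALSE) {
  res <- strsplit(as_residues(chain), "")[[1]]
  n <- length(res)
  idx <- scan_positions(chain, include_thr = include_thr)
  keep <- vapply(idx, function(i) {
    win <- i + 5:7
    win <- win[win <= n]
    if (length(win) == 0) return(FALSE)
    acidic <- res[win] %in% c("D", "E")
    ok <- if (require_all_acidic) length(win) == 3 && all(acidic) else any(acidic)
    if (require_q) ok <- ok && i + 2 <= n && res[i + 2] == "Q"
    ok
  }, logical(1))
  chain_offset(chain) + idx[keep] - 1L
}

#' Annotate every Ser/Thr of a chain with its motif context
#'
#' Runs all motif scanners and returns one row per serine (and threonine when
#' `include_thr = TRUE`) with logical motif-class columns, ready to join
#' against a phosphosite map.
#'
#' @inheritParams scan_extended
#' @inheritParams scan_acidic_context
#' @return A tibble: `position`, `residue`, `sxe`, `sxps` (extended-motif
#'   membership given `phospho_positions`), `sxd`, `acidic_n5_n7`.
#' @export
annotate_sites <- function(chain, phospho_positions = integer(),
                           include_thr = FALSE,
                           require_q = FALSE, require_all_acidic = FALSE) {
  pos_tab <- chain_positions(chain)
  targets <- if (include_thr) c("S", "T") else "S"
  pos_tab <- filter(pos_tab, .data$residue %in% targets)
  sxe <- scan_canonical(chain, include_thr)
  ext <- scan_extended(chain, phospho_positions, include_thr)
  mutate(
    select(pos_tab, "position", "residue"),
    sxe = .data$position %in% sxe,
    sxps = .data$position %in% setdiff(ext, sxe),
    sxd = .data$position %in% scan_sxd(chain, include_thr),
    acidic_n5_n7 = .data$position %in%
      scan_acidic_context(chain, include_thr, require_q, require_all_acidic)
  )
}
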