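#' Coerce an alignment to a named character vector
#'
#' Accepts a named character vector of equal-length gapped sequences, a data
#' frame with `id` and `sequence` columns, or a `Biostrings` `AAStringSet` /
#' `AAMultipleAlignment`. The gap character is `-`.
#'
#' @param x Alignment in any supported form.
#' @return Named character vector of gapped sequences (equal widths).
#' @export
as_alignment <- function(x) {
  if (inherits(x, "AAMultipleAlignment")) {
    x <- methods::as(x, "AAStringSet")
  }
  if (inherits(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    x <- setNames(as.character(x$sequence), as.character(x$id))
  }
  if (!is.character(x) || is.null(names(x))) {
    abort("alignment must be a named character vector (or coercible to one)")
  }
  x <- toupper(x)
  if (length(x) < 2) abort("alignment needs at least 2 records")
  if (length(unique(nchar(x))) != 1) abort("alignment records must have equal gapped length")
  x
}

#' Map a reference position to its alignment column
#'
#' @param aln Alignment (see [as_alignment()]).
#' @param ref_id Identifier of the reference record.
#' @param ref_pos Position(s) in the ungapped reference sequence (1-based).
#' @return Integer column index/indices.
#' @examples
#' map_position_to_column(c(ref = "A-CD", other = "ABCD"), "ref", 2)  # -> 3
#' @export
map_position_to_column <- function(aln, ref_id, ref_pos) {
  aln <- as_alignment(aln)
  if (!ref_id %in% names(aln)) abort(sprintf("reference '%s' not in alignment", ref_id))
  ref <- strsplit(aln[[ref_id]], "")[[1]]
  cols <- which(ref != "-")
  ref_pos <- as.integer(ref_pos)
  if (any(ref_pos < 1 | ref_pos > length(cols))) {
    abort(sprintf("reference position out of range (ungapped length %d)", length(cols)))
  }
  cols[ref_pos]
}

#' Per-site conservation across an ortholog family
#'
#' For each reference phosphosite, maps the position into the alignment and
#' reports the percentage of records (reference included in the denominator)
#' that carry the identical residue at that column. A gap counts as a
#' non-match, and so does a conservative substitution (an aligned Thr does
#' not count for a Ser site): the question asked is whether the species
#' retains the specific phospho-acceptor. Percentages are rounded half away
#' from zero to integers, the granularity at which such tables are reported
#' (13/14 -> 93).
#'
#' @param aln Alignment (see [as_alignment()]).
#' @param ref_id Reference record identifier.
#' @param sites Integer positions in the ungapped reference.
#' @return A tibble: `position`, `column`, `ref_residue`, `n_match`,
#'   `n_total`, `conservation` (integer percent), `matches` (list column of
#'   named logicals per record).
#' @export
site_conservation <- function(aln, ref_id, sites) {
  aln <- as_alignment(aln)
  sites <- as.integer(sites)
  cols <- map_position_to_column(aln, ref_id, sites)
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(mat) <- names(aln)
  ref_res <- mat[ref_id, cols]
  out <- purrr::map2(cols, ref_res, function(co, rr) {
    m <- mat[, co] == rr
    list(n_match = sum(m), flags = m)
  })
  n_total <- length(aln)
  tibble(
    position = sites,
    column = cols,
    ref_residue = unname(ref_res),
    n_match = vapply(out, function(o) as.integer(o$n_match), integer(1)),
    n_total = n_total,
    conservation = as.integer(round_half_up(
      100 * vapply(out, function(o) o$n_match, numeric(1)) / n_total
    )),
    matches = lapply(out, function(o) o$flags)
  )
}
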