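#' Protein chains with printed-position bookkeeping
#'
#' A `protein_chain` is a stretch of amino acids together with the position
#' that is printed for its first residue. Mature human MEPE is numbered
#' 1--508, but tryptic peptides and C-terminal fragments are routinely
#' discussed with their own printed spans (e.g. residues 489--508), so the
#' chain keeps a `numbering_offset`: the printed position of residue `i` is
#' `numbering_offset + i - 1`.
#'
#' @param residues Character scalar of one-letter amino-acid codes (the 20
#'   canonical letters).
#' @param id Chain identifier.
#' @param numbering_offset Printed position of the first residue (default 1).
#' @return An object of class `protein_chain`.
#' @examples
#' asarm <- protein_chain("RRDDSSESSDSGSSSESDGD", id = "MEPE_489_508",
#'                        numbering_offset = 489)
#' chain_length(asarm)
#' @export
protein_chain <- function(residues, id = "chain", numbering_offset = 1L) {
  residues <- toupper(as.character(residues))
  stopifnot(length(residues) == 1L, nchar(residues) >= 1L)
  letters_seen <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters_seen), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("non-canonical residue letter(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      id = as.character(id),
      residues = residues,
      numbering_offset = as.integer(numbering_offset)
    ),
    class = "protein_chain"
  )
}

#' @export
print.protein_chain <- function(x, ...) {
  n <- chain_length(x)
  cat(sprintf(
    "<protein_chain> %s: %d aa, printed positions %d-%d\n",
    x$id, n, x$numbering_offset, x$numbering_offset + n - 1L
  ))
  seq <- x$residues
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat(" ", seq, "\n")
  invisible(x)
}

#' @rdname protein_chain
#' @param x A `protein_chain`.
#' @export
chain_length <- function(x) nchar(as_residues(x))

# Accept a chain or a bare string wherever a sequence is needed.
as_residues <- function(x) {
  if (inherits(x, "protein_chain")) x$residues else toupper(as.character(x))
}

chain_offset <- function(x) {
  if (inherits(x, "protein_chain")) x$numbering_offset else 1L
}

#' Per-residue coordinate table of a chain
#'
#' @param chain A `protein_chain`.
#' @return A tibble with one row per residue: `position` (printed numbering),
#'   `index` (1-based within the chain) and `residue`.
#' @export
chain_positions <- function(chain) {
  res <- strsplit(as_residues(chain), "")[[1]]
  tibble(
    position = chain_offset(chain) + seq_along(res) - 1L,
    index = seq_along(res),
    residue = res
  )
}

#' Look up the residue printed at a given position
#'
#' @param chain A `protein_chain`.
#' @param position Printed position(s).
#' @return Character vector of residue letters.
#' @export
residue_at <- function(chain, position) {
  idx <- as.integer(position) - chain_offset(chain) + 1L
  n <- chain_length(chain)
  if (any(idx < 1L | idx > n)) {
    abort(sprintf("position out of range for chain '%s'",
                  if (inherits(chain, "protein_chain")) chain$id else "<string>"))
  }
  vapply(idx, function(i) substr(as_residues(chain), i, i), character(1))
}

#' Parse point-mutation shorthand
#'
#' Accepts the field's usual `"K509A"` notation (wild-type residue, printed
#' position, replacement residue) and returns a tidy mutation table.
#'
#' @param x Character vector such as `c("K509A", "K515A")`, or a data frame
#'   already holding `position`, `from`, `to`.
#' @return A tibble with columns `position`, `from`, `to`.
#' @export
parse_mutations <- function(x) {
  if (is.data.frame(x)) {
    out <- as_tibble(x)
    stopifnot(all(c("position", "from", "to") %in% names(out)))
    return(mutate(out, position = as.integer(.data$position)))
  }
  if (length(x) == 0) {
    return(tibble(position = integer(), from = character(), to = character()))
  }
  m <- stringr::str_match(toupper(x), "^([A-Z])(\\d+)([A-Z])$")
  if (anyNA(m[, 1])) {
    abort(paste0("cannot parse mutation(s): ",
                 paste(x[is.na(m[, 1])], collapse = ", ")))
  }
  tibble(position = as.integer(m[, 3]), from = m[, 2], to = m[, 4])
}

#' Apply point mutations to a chain
#'
#' Each mutation's wild-type letter is checked against the chain before any
#' edit is made; a mismatch aborts with the offending printed position, so a
#' construct description cannot silently drift out of register with its
#' sequence.
#'
#' @param chain A `protein_chain`.
#' @param mutations Mutations in `parse_mutations()` notation or as a tidy
#'   table. Positions are printed positions.
#' @return The mutated `protein_chain` (same id, offset and length).
#' @examples
#' tail <- protein_chain("KLGPEQKLISEEDL", numbering_offset = 509)
#' apply_mutations(tail, c("K509A", "K515A"))
#' @export
apply_mutations <- function(chain, mutations) {
  stopifnot(inherits(chain, "protein_chain"))
  muts <- parse_mutations(mutations)
  if (nrow(muts) == 0) return(chain)
  res <- strsplit(chain$residues, "")[[1]]
  idx <- muts$position - chain$numbering_offset + 1L
  if (any(idx < 1L | idx > length(res))) {
    abort(sprintf("mutation position(s) %s outside chain '%s'",
                  paste(muts$position[idx < 1L | idx > length(res)], collapse = ", "),
                  chain$id))
  }
  actual <- res[idx]
  bad <- actual != muts$from
  if (any(bad)) {
    abort(sprintf(
      "wild-type residue mismatch at printed position(s) %s: expected %s, found %s",
      paste(muts$position[bad], collapse = ", "),
      paste(muts$from[bad], collapse = ", "),
      paste(actual[bad], collapse = ", ")
    ))
  }
  res[idx] <- muts$to
  protein_chain(paste(res, collapse = ""), id = chain$id,
                numbering_offset = chain$numbering_offset)
}

#' Describe a recombinant construct
#'
#' A construct is a base chain followed by ordered tag segments (for the MEPE
#' study system: linker `KLGP`, the myc epitope `EQKLISEEDL`, linker `NSAVD`
#' and a His6 tag), with point mutations applied after assembly. Printed
#' numbering continues from the base chain into the tags, which is how the
#' K509A/K515A lysine substitutions are addressed (mature MEPE ends at 508).
#'
#' @param base A `protein_chain`.
#' @param tags Named character vector or list of tag segments, in order.
#' @param mutations Point mutations in `"K509A"` shorthand (printed,
#'   tag-extended numbering) or a tidy table; default none.
#' @param id Construct identifier.
#' @return An object of class `construct`.
#' @export
construct <- function(base, tags = character(), mutations = character(),
                      id = paste0(base$id, "_construct")) {
  stopifnot(inherits(base, "protein_chain"))
  tags <- unlist(tags)
  if (length(tags) > 0 && is.null(names(tags))) {
    names(tags) <- paste0("tag", seq_along(tags))
  }
  structure(
    list(base = base, tags = tags, mutations = parse_mutations(mutations), id = id),
    class = "construct"
  )
}

#' @export
print.construct <- function(x, ...) {
  cat(sprintf("<construct> %s: base %s (%d aa) + %d tag segment(s), %d mutation(s)\n",
              x$id, x$base$id, chain_length(x$base), length(x$tags), nrow(x$mutations)))
  invisible(x)
}

#' Assemble a construct into a single chain with a coordinate table
#'
#' Concatenates base and tag segments, applies the construct's point
#' mutations, and attaches a coordinate table (`construct_coordinates()`)
#' mapping every residue to its segment, segment-local index and continuous
#' printed position.
#'
#' @param x A `construct`.
#' @return A `protein_chain` whose `"coordinates"` attribute holds the table.
#' @examples
#' base <- protein_chain("RRDDSSESSDSGSSSESDGD", id = "MEPE_C489",
#'                       numbering_offset = 489)
#' cons <- construct(base,
#'   tags = c(linker1 = "KLGP", myc = "EQKLISEEDL",
#'            linker2 = "NSAVD", his6 = "HHHHHH"),
#'   mutations = c("K509A", "K515A"))
#' assemble_construct(cons)
#' @export
assemble_construct <- function(x) {
  stopifnot(inherits(x, "construct"))
  segs <- c(setNames(list(x$base$residues), "mature"), as.list(x$tags))
  seq_full <- paste(unlist(segs), collapse = "")
  chain <- protein_chain(seq_full, id = x$id,
                         numbering_offset = x$base$numbering_offset)
  if (nrow(x$mutations) > 0) chain <- apply_mutations(chain, x$mutations)
  lens <- vapply(segs, nchar, integer(1))
  coords <- tibble(
    position = chain_offset(chain) + seq_len(sum(lens)) - 1L,
    segment = rep(names(segs), lens),
    local_index = unlist(lapply(lens, seq_len), use.names = FALSE),
    residue = strsplit(chain$residues, "")[[1]]
  )
  attr(chain, "coordinates") <- coords
  chain
}

#' @rdname assemble_construct
#' @param chain A chain returned by `assemble_construct()`.
#' @export
construct_coordinates <- function(chain) {
  coords <- attr(chain, "coordinates")
  if (is.null(coords)) abort("chain carries no coordinate table; assemble a construct first")
  coords
}

#' Extract a region of a chain by printed positions
#'
#' @param chain A `protein_chain`.
#' @param start,end Printed positions, 1-based inclusive.
#' @return Character scalar with the region's residues.
#' @examples
#' asarm <- protein_chain("RRDDSSESSDSGSSSESDGD", numbering_offset = 489)
#' extract_region(asarm, 493, 495)
#' @export
extract_region <- function(chain, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  off <- chain_offset(chain); n <- chain_length(chain)
  if (start > end) abort("region start must not exceed end")
  i <- start - off + 1L; j <- end - off + 1L
  if (i < 1L || j > n) {
    abort(sprintf("region %d-%d outside chain (printed span %d-%d)",
                  start, end, off, off + n - 1L))
  }
  substr(as_residues(chain), i, j)
}
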