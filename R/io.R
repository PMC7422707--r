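#' Read and write FASTA sequence files
#'
#' Thin wrappers around `Biostrings` for plain and aligned amino-acid FASTA.
#' `read_fasta()` returns `protein_chain` objects; `read_alignment()` keeps
#' gaps and returns the named character vector used by the conservation
#' functions.
#'
#' @param path File path.
#' @param numbering_offset Printed position of residue 1 for every chain
#'   read (default 1).
#' @return `read_fasta()`: a list of `protein_chain`; `read_alignment()`:
#'   a named character vector of gapped sequences.
#' @export
read_fasta <- function(path, numbering_offset = 1L) {
  seqs <- Biostrings::readAAStringSet(path)
  purrr::imap(
    setNames(as.character(seqs), names(seqs)),
    ~ protein_chain(.x, id = sub("\\s.*$", "", .y), numbering_offset = numbering_offset)
  )
}

#' @rdname read_fasta
#' @param chains A `protein_chain`, list of them, or named character vector.
#' @export
write_fasta <- function(chains, path) {
  if (inherits(chains, "protein_chain")) chains <- list(chains)
  if (is.character(chains)) {
    seqs <- chains
  } else {
    seqs <- setNames(
      vapply(chains, as_residues, character(1)),
      vapply(chains, function(c) c$id, character(1))
    )
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  as_alignment(setNames(as.character(seqs), sub("\\s.*$", "", names(seqs))))
}

#' @rdname read_fasta
#' @param aln Alignment coercible by [as_alignment()].
#' @export
write_alignment <- function(aln, path) {
  write_fasta(as_alignment(aln), path)
}

#' Read and write two-column peak lists
#'
#' Peak lists are delimited text with columns `mz` and `intensity`
#' (tab-separated; a header line is expected).
#'
#' @param path File path.
#' @return A peak-list tibble (see [as_peaklist()]).
#' @export
read_peaklist <- function(path) {
  as_peaklist(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_peaklist
#' @param peaks Peak list coercible by [as_peaklist()].
#' @export
write_peaklist <- function(peaks, path) {
  readr::write_tsv(as_peaklist(peaks), path)
  invisible(path)
}

#' Read and write phosphopeptide evidence tables
#'
#' Evidence tables are tab-separated with columns `peptide`, `start`, `end`,
#' `phospho` (events separated by `";"`, either-or candidates by `"|"`),
#' `counts`, and optional `expect`, `ppm`, `conservation`. The packaged
#' transcription of the study's LC-MS/MS phosphopeptide table ships in this
#' format (`mepe_fixture("mepe_lcms_evidence.tsv")`).
#'
#' @param path File path.
#' @return A tibble of evidence rows suitable for [collate_lcms()].
#' @export
read_evidence <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    peptide = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    phospho = readr::col_character(),
                    counts = readr::col_integer(),
                    .default = readr::col_guess()
                  ))
}

#' @rdname read_evidence
#' @param evidence Evidence tibble.
#' @export
write_evidence <- function(evidence, path) {
  readr::write_tsv(as_tibble(evidence), path)
  invisible(path)
}

#' Read a construct description file
#'
#' Construct descriptions are small YAML files naming the base chain (id,
#' residues, numbering offset), the ordered tag segments, mutations in
#' `"K509A"` shorthand, and optionally named regions (e.g. the ASARM span).
#'
#' @param path YAML file path.
#' @return A `construct`; named regions, if any, are attached as a tibble in
#'   the `"regions"` attribute.
#' @export
read_construct <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- protein_chain(cfg$base$residues, id = cfg$base$id %||% "base",
                        numbering_offset = cfg$base$offset %||% 1L)
  tags <- if (length(cfg$tags) > 0) {
    setNames(
      vapply(cfg$tags, function(t) t$residues, character(1)),
      vapply(cfg$tags, function(t) t$name, character(1))
    )
  } else character()
  out <- construct(base, tags = tags,
                   mutations = unlist(cfg$mutations) %||% character(),
                   id = cfg$id %||% paste0(base$id, "_construct"))
  if (length(cfg$regions) > 0) {
    attr(out, "regions") <- purrr::map_dfr(cfg$regions, ~ tibble(
      name = .x$name, start = as.integer(.x$start), end = as.integer(.x$end)
    ))
  }
  out
}

#' Path to a packaged fixture file
#'
#' @param file Fixture file name; with no argument, the fixture directory.
#' @return File path inside the installed package.
#' @export
mepe_fixture <- function(file = "") {
  system.file("extdata", file, package = "mepephos", mustWork = TRUE)
}
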