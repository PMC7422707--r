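# Parse a phospho-event string: events separated by ";", candidates of an
# ambiguous either-or pair separated by "|". "436;441" = two resolved sites
# on one peptide; "103|104" = one phosphate on one of two residues.
parse_phospho_events <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(evs) {
    lapply(strsplit(trimws(evs), "|", fixed = TRUE), function(p) {
      sort(as.integer(p))
    })
  })
}

site_key <- function(positions) paste(sort(positions), collapse = "|")

new_site_map <- function(rows, n_tag_phospho = 0L, maldi_note = NULL) {
  out <- arrange(rows, .data$position)
  structure(out,
            class = c("site_map", class(as_tibble(out))),
            n_tag_phospho = n_tag_phospho,
            maldi_note = maldi_note)
}

empty_site_map <- function() {
  new_site_map(tibble(
    site = character(), position = integer(), positions = list(),
    residue = character(), ambiguous = logical(), status = character(),
    source = character(), spectral_count = integer(), n_rows = integer(),
    major = logical()
  ))
}

#' Collate peptide-level phosphosite evidence into a residue-level site map
#'
#' Each evidence row is one identified phosphopeptide with one or more
#' phospho events; an ambiguous either-or pair (a phosphate that could not
#' be localized between two neighbouring acceptors) is a single event and
#' contributes exactly one site to all totals. Aggregated spectral counts
#' per site take the maximum over rows containing the site, because the
#' per-row counts already accumulate all identified peptides containing that
#' residue — summing would double-count.
#'
#' @param evidence A tibble with columns `peptide` (residue string), `start`,
#'   `end` (printed positions of the peptide span), `phospho` (event string:
#'   events separated by `";"`, either-or candidates by `"|"`, e.g.
#'   `"436;441"` or `"103|104"`), `counts` (spectral count); optional
#'   `expect`, `ppm`, `conservation` metadata are carried along. See
#'   [read_evidence()].
#' @param parent Optional `protein_chain`; when supplied, each row's peptide
#'   is checked against the parent sequence and inconsistent rows are dropped
#'   with a warning naming them.
#' @return A `site_map` tibble with one row per site unit: `site` (label,
#'   `"103|104"` for ambiguous pairs), `position` (first candidate, for
#'   ordering), `positions` (list column), `residue` (`"S"`, `"T"`, or
#'   `"S|T"` for an ambiguous pair spanning both), `ambiguous`, `status`,
#'   `source`, `spectral_count`, `n_rows`, `major` (filled by
#'   [flag_major_sites()]).
#' @export
collate_lcms <- function(evidence, parent = NULL) {
  ev <- as_tibble(evidence)
  if (nrow(ev) == 0) return(empty_site_map())
  needed <- c("peptide", "start", "end", "phospho", "counts")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols) > 0) {
    abort(paste0("evidence table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ev <- mutate(ev, peptide = toupper(.data$peptide),
               start = as.integer(.data$start), end = as.integer(.data$end),
               counts = as.integer(.data$counts))

  bad_len <- nchar(ev$peptide) != ev$end - ev$start + 1L
  if (any(bad_len)) {
    abort(sprintf("peptide length disagrees with span in row(s) %s",
                  paste(which(bad_len), collapse = ", ")))
  }
  if (!is.null(parent)) {
    ok <- vapply(seq_len(nrow(ev)), function(i) {
      identical(extract_region(parent, ev$start[i], ev$end[i]), ev$peptide[i])
    }, logical(1))
    if (any(!ok)) {
      warn(sprintf("dropping %d evidence row(s) inconsistent with parent '%s': row(s) %s",
                   sum(!ok), parent$id, paste(which(!ok), collapse = ", ")))
      ev <- ev[ok, , drop = FALSE]
      if (nrow(ev) == 0) return(empty_site_map())
    }
  }

  events <- parse_phospho_events(ev$phospho)
  units <- purrr::map_dfr(seq_len(nrow(ev)), function(i) {
    purrr::map_dfr(events[[i]], function(pos) {
      if (any(pos < ev$start[i] | pos > ev$end[i])) {
        abort(sprintf("phospho position(s) %s outside peptide span %d-%d (row %d)",
                      paste(pos, collapse = "|"), ev$start[i], ev$end[i], i))
      }
      res <- substring(ev$peptide[i], pos - ev$start[i] + 1L, pos - ev$start[i] + 1L)
      bad <- !res %in% c("S", "T", "Y")
      if (any(bad)) {
        abort(sprintf("phospho position %d (row %d) is %s, not a phospho-acceptor",
                      pos[bad][1], i, res[bad][1]))
      }
      tibble(key = site_key(pos), positions = list(pos),
             residue = paste(unique(res), collapse = "|"),
             counts = ev$counts[i])
    })
  })

  rows <- units |>
    group_by(.data$key) |>
    summarise(
      positions = .data$positions[1],
      residue = .data$residue[1],
      spectral_count = max(.data$counts),
      n_rows = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      site = .data$key,
      position = vapply(.data$positions, min, integer(1)),
      ambiguous = lengths(.data$positions) > 1L,
      status = "phosphorylated",
      source = "LC-MS/MS",
      major = FALSE
    ) |>
    select("site", "position", "positions", "residue", "ambiguous",
           "status", "source", "spectral_count", "n_rows", "major")
  new_site_map(rows)
}

#' @export
print.site_map <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<site_map> %d site(s): Ser %s, Thr %s; %d ambiguous pair(s); %d major; sources: %s\n",
    g$grand_total,
    if (g$n_ser_min == g$n_ser_max) g$n_ser_min else paste0(g$n_ser_min, "-", g$n_ser_max),
    if (g$n_thr_min == g$n_thr_max) g$n_thr_min else paste0(g$n_thr_min, "-", g$n_thr_max),
    sum(x$ambiguous), sum(x$major),
    paste(unique(x$source), collapse = ", ")
  ))
  NextMethod()
}

#' Major-site classification by spectral count
#'
#' Spectral counts proxy site abundance; sites at or above the threshold are
#' called major phosphorylation sites. The default threshold of 20 separates
#' the high-count sites of the packaged evidence (counts 20--39) from the
#' rest (at most 7).
#'
#' `classify_major()` returns the major positions; `flag_major_sites()`
#' returns the map with its `major` column set.
#'
#' @param map A `site_map`.
#' @param threshold Minimum aggregated spectral count (default 20).
#' @return `classify_major()`: sorted integer positions (both candidates of
#'   an ambiguous pair, should one qualify, with a warning).
#'   `flag_major_sites()`: the updated `site_map`.
#' @export
classify_major <- function(map, threshold = 20L) {
  stopifnot(threshold >= 1)
  hit <- map$status == "phosphorylated" & !is.na(map$spectral_count) &
    map$spectral_count >= threshold
  if (any(hit & map$ambiguous)) {
    warn("ambiguous site pair(s) reach the major-site threshold; both candidates returned")
  }
  sort(unique(as.integer(unlist(map$positions[hit]))))
}

#' @rdname classify_major
#' @export
flag_major_sites <- function(map, threshold = 20L) {
  major_pos <- classify_major(map, threshold)
  map$major <- vapply(map$positions, function(p) any(p %in% major_pos), logical(1))
  map
}

#' Merge a region-level MALDI ladder result into a site map
#'
#' Intact-mass ladders count phosphates but do not localize them. When the
#' maximum ladder count (minus any phosphates attributed to tag serines,
#' e.g. the one observed in the myc epitope) covers every serine of the
#' region, all region serines are marked phosphorylated at region-level
#' ("assumed") resolution with source MALDI; otherwise the map is returned
#' unchanged apart from a note recording the partial coverage.
#'
#' @param map A `site_map` (typically from [collate_lcms()]).
#' @param region_serines Printed positions of the region's serines.
#' @param ladder_max Maximum phosphate count assigned to the ladder.
#' @param tag_phospho Number of ladder phosphates attributed to tag residues
#'   outside the mature chain (default 1, the myc-tag phosphosite); these are
#'   reserved before region serines are covered and are excluded from mature
#'   totals.
#' @return The augmented `site_map`.
#' @export
merge_maldi <- function(map, region_serines, ladder_max, tag_phospho = 1L) {
  stopifnot(ladder_max >= 0)
  region_serines <- sort(as.integer(region_serines))
  available <- ladder_max - tag_phospho
  if (length(region_serines) == 0 || available < length(region_serines)) {
    note <- sprintf(
      "ladder supports %d mature-region phosphate(s) for %d region serine(s); no site-level assignment",
      max(available, 0L), length(region_serines))
    attr(map, "maldi_note") <- note
    attr(map, "n_tag_phospho") <- as.integer(tag_phospho)
    return(map)
  }
  existing <- unlist(map$positions)
  overlap <- intersect(region_serines, existing)
  if (length(overlap) > 0) {
    map$source[vapply(map$positions, function(p) any(p %in% overlap), logical(1))] <- "both"
  }
  add <- setdiff(region_serines, existing)
  new_rows <- tibble(
    site = as.character(add), position = add,
    positions = lapply(add, identity),
    residue = "S", ambiguous = FALSE,
    status = "assumed (region-level)", source = "MALDI",
    spectral_count = NA_integer_, n_rows = 1L, major = FALSE
  )
  new_site_map(bind_rows(as_tibble(map), new_rows),
               n_tag_phospho = as.integer(tag_phospho),
               maldi_note = sprintf(
                 "ladder max %d covers all %d region serines (+%d tag phosphate(s))",
                 ladder_max, length(region_serines), tag_phospho))
}

#' Headline totals of a site map
#'
#' @param map A `site_map`.
#' @return One-row tibble: `n_lcms` (sites with LC-MS/MS evidence),
#'   `n_maldi_region` (region-level MALDI sites), `grand_total` (distinct
#'   mature-chain site units across sources; tag phosphates are reported
#'   separately in `n_tag_phospho` and excluded from the grand total).
#' @export
site_totals <- function(map) {
  tibble(
    n_lcms = sum(map$source %in% c("LC-MS/MS", "both")),
    n_maldi_region = sum(map$source == "MALDI"),
    grand_total = nrow(map),
    n_tag_phospho = attr(map, "n_tag_phospho") %||% 0L
  )
}

# Ser/Thr tallies as min-max ranges: an ambiguous S|T pair could resolve
# either way, so it widens both ranges by one.
residue_tally <- function(map) {
  cand <- strsplit(map$residue, "|", fixed = TRUE)
  always_s <- vapply(cand, function(r) all(r == "S"), logical(1))
  maybe_s <- vapply(cand, function(r) any(r == "S"), logical(1))
  always_t <- vapply(cand, function(r) all(r == "T"), logical(1))
  maybe_t <- vapply(cand, function(r) any(r == "T"), logical(1))
  tibble(
    n_ser_min = sum(always_s), n_ser_max = sum(maybe_s),
    n_thr_min = sum(always_t), n_thr_max = sum(maybe_t)
  )
}
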