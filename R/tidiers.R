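#' Tidy a site map into one row per candidate residue
#'
#' Unnests ambiguous pairs so every candidate position has its own row
#' (flagged by `ambiguity_group`); [glance.site_map()] gives the one-row
#' summary with Ser/Thr ranges and totals.
#'
#' @param x A `site_map`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `residue`, `ambiguity_group`,
#'   `status`, `source`, `spectral_count`, `major`.
#' @export
tidy.site_map <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    pos <- x$positions[[i]]
    res <- strsplit(x$residue[i], "|", fixed = TRUE)[[1]]
    if (length(res) == 1) res <- rep(res, length(pos))
    tibble(
      position = pos,
      residue = res,
      ambiguity_group = if (x$ambiguous[i]) x$site[i] else NA_character_,
      status = x$status[i],
      source = x$source[i],
      spectral_count = x$spectral_count[i],
      major = x$major[i]
    )
  })
}

#' @rdname tidy.site_map
#' @export
glance.site_map <- function(x, ...) {
  dplyr::bind_cols(site_totals(x), residue_tally(x),
                   tibble(n_ambiguous = sum(x$ambiguous),
                          n_major = sum(x$major)))
}

#' Tidy / summarise a reproduction report
#'
#' `tidy()` returns the per-check table (recomputed value, expected value,
#' pass flag); `glance()` returns the headline numbers in one row.
#'
#' @param x A `repro_report` from [reproduce()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.repro_report <- function(x, ...) x$checks

#' @rdname tidy.repro_report
#' @export
glance.repro_report <- function(x, ...) {
  tibble(
    cterm_mass_mh = x$cterm_mass,
    ladder_max = max_phospho(x$assignments),
    n_lcms_sites = x$totals$n_lcms,
    n_maldi_sites = x$totals$n_maldi_region,
    grand_total = x$totals$grand_total,
    n_major = length(x$major_sites),
    all_pass = all(x$checks$pass)
  )
}
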