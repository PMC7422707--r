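#' Coerce peak-list input
#'
#' Accepts a numeric vector of m/z values or a data frame with columns
#' `mz` (required) and `intensity` (optional).
#'
#' @param x Peaks as numeric vector or data frame.
#' @return A tibble with columns `mz` and `intensity`.
#' @export
as_peaklist <- function(x) {
  if (is.numeric(x)) {
    out <- tibble(mz = as.double(x), intensity = NA_real_)
  } else {
    out <- as_tibble(x)
    if (!"mz" %in% names(out)) abort("peak list needs an 'mz' column")
    if (!"intensity" %in% names(out)) out$intensity <- NA_real_
    out <- select(out, "mz", "intensity")
    out$mz <- as.double(out$mz)
  }
  if (any(out$mz <= 0, na.rm = TRUE)) abort("m/z values must be positive")
  out
}

#' Assign observed peaks to a phospho-ladder
#'
#' Matches each observed peak to the nearest rung of the theoretical ladder
#' `base + k * delta` and keeps the assignment when the mass error is within
#' tolerance. A peak exactly equidistant from two rungs takes the lower
#' phosphate count (conservative). The default tolerance is 0.1% of m/z,
#' appropriate for externally calibrated linear-mode MALDI (~5 Da at 5 kDa;
#' the study's own observed-vs-theoretical gaps are 1.6--3.3 Da).
#'
#' @param peaks Peak list (see [as_peaklist()]).
#' @param base_mass Unmodified-species mass on the same charge convention as
#'   the peaks (MH+ for MALDI).
#' @param n_max Highest phosphate count considered; default spans the
#'   observed mass range.
#' @param tolerance Match tolerance; relative fraction of m/z when
#'   `tolerance_type = "relative"` (default 0.001), absolute Da otherwise.
#' @param tolerance_type `"relative"` or `"dalton"`.
#' @param type Mass scale for the phosphate increment, `"average"` default.
#' @param intensity_floor Peaks with intensity strictly below this are
#'   dropped before matching (default `NULL`: no floor).
#' @return A `ladder_assignment` tibble: `mz`, `intensity`, `n_phospho`
#'   (integer, `NA` when unassigned), `theoretical`, `error_da`, `error_ppm`,
#'   `assigned`.
#' @examples
#' assign_phospho_ladder(c(4840.4, 5640.8), base_mass = 4838.8)
#' @export
assign_phospho_ladder <- function(peaks, base_mass,
                                  n_max = NULL,
                                  tolerance = 0.001,
                                  tolerance_type = c("relative", "dalton"),
                                  type = c("average", "monoisotopic"),
                                  intensity_floor = NULL) {
  tolerance_type <- match.arg(tolerance_type)
  type <- match.arg(type)
  stopifnot(base_mass > 0, tolerance > 0)
  pk <- as_peaklist(peaks)
  if (!is.null(intensity_floor)) {
    pk <- filter(pk, is.na(.data$intensity) | .data$intensity >= intensity_floor)
  }
  delta <- phospho_delta(type)
  if (is.null(n_max)) {
    n_max <- if (nrow(pk) == 0) 0L else
      max(0L, ceiling((max(pk$mz) - base_mass) / delta) + 1L)
  }
  ladder <- phospho_ladder(base_mass, n_max, type)
  out <- pk
  if (nrow(pk) == 0) {
    out$n_phospho <- integer()
    out$theoretical <- double()
    out$error_da <- double()
    out$error_ppm <- double()
    out$assigned <- logical()
  } else {
    # nearest rung; ties broken toward the lower phosphate count
    k_near <- vapply(pk$mz, function(m) {
      d <- abs(ladder$mass - m)
      ladder$n_phospho[which.min(d)]   # which.min returns first (lowest k) on ties
    }, integer(1))
    theo <- base_mass + k_near * delta
    err <- pk$mz - theo
    tol_da <- if (tolerance_type == "relative") tolerance * pk$mz else rep(tolerance, nrow(pk))
    ok <- abs(err) <= tol_da
    out$n_phospho <- ifelse(ok, k_near, NA_integer_)
    out$theoretical <- ifelse(ok, theo, NA_real_)
    out$error_da <- ifelse(ok, err, NA_real_)
    out$error_ppm <- ifelse(ok, 1e6 * err / theo, NA_real_)
    out$assigned <- ok
  }
  structure(out,
            class = c("ladder_assignment", class(out)),
            base_mass = base_mass, delta = delta,
            tolerance = tolerance, tolerance_type = tolerance_type)
}

#' Maximum assigned phosphate count
#'
#' @param assignments A `ladder_assignment` table (or any table with an
#'   `n_phospho` column).
#' @return Integer: the highest assigned count, 0 when nothing is assigned.
#' @export
max_phospho <- function(assignments) {
  k <- assignments$n_phospho
  k <- k[!is.na(k)]
  if (length(k) == 0) 0L else max(as.integer(k))
}

#' Dephosphorylation (alkaline phosphatase) control
#'
#' A phospho-ladder is accepted as phosphorylation evidence only if enzymatic
#' dephosphorylation collapses it: the control passes when the untreated
#' spectrum shows at least one peak with k > 0 phosphates and every assigned
#' peak after treatment has k = 0 (the unmodified mass).
#'
#' @param before,after Peak lists before and after phosphatase treatment.
#' @param base_mass Unmodified-species mass (MH+ convention).
#' @param ... Passed to [assign_phospho_ladder()] (tolerance etc.).
#' @return One-row tibble: `pass`, `max_phospho_before`, `max_phospho_after`,
#'   `n_assigned_before`, `n_assigned_after`, `after_all_unmodified`.
#' @export
dephospho_control <- function(before, after, base_mass, ...) {
  a_before <- assign_phospho_ladder(before, base_mass, ...)
  a_after <- assign_phospho_ladder(after, base_mass, ...)
  k_after <- a_after$n_phospho[!is.na(a_after$n_phospho)]
  after_clean <- length(k_after) > 0 && all(k_after == 0L)
  had_phospho <- max_phospho(a_before) > 0L
  tibble(
    pass = had_phospho && after_clean,
    max_phospho_before = max_phospho(a_before),
    max_phospho_after = max_phospho(a_after),
    n_assigned_before = sum(a_before$assigned),
    n_assigned_after = sum(a_after$assigned),
    after_all_unmodified = after_clean
  )
}
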