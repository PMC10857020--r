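# Wavelength-importance analysis: median regression-coefficient (RC) and
# VIP profiles across the cross-validation models, local peak detection,
# and cross-dataset peak matching.

#' Median RC and VIP profiles across CV models
#'
#' Each model contributes its regression coefficients and VIP scores at its
#' own tuned component count; the per-wavelength median over all models
#' (25 at the default scheme) is the dataset's importance profile.
#'
#' @param models list of `plsr_model` objects sharing one wavelength grid.
#' @return A list of class `importance_profile`: `wavelengths`,
#'   `median_rc`, `median_vip`.
#' @export
median_profiles <- function(models) {
  wl <- models[[1]]$wavelengths
  for (m in models)
    if (length(m$wavelengths) != length(wl) ||
        max(abs(m$wavelengths - wl)) > 1e-8)
      stop("models do not share a wavelength grid")
  rc <- vapply(models, regression_coefficients, numeric(length(wl)))
  vp <- vapply(models, vip, numeric(length(wl)))
  structure(list(wavelengths = wl,
                 median_rc = apply(rc, 1, median),
                 median_vip = apply(vp, 1, median)),
            class = "importance_profile")
}

#' Detect local peaks in an importance profile
#'
#' A point is a peak iff it is the strict extremum within the centered
#' window of full width `span_nm` (clipped at grid-segment edges; dead
#' bands are never bridged; segment endpoints are not candidates). Ties go
#' to the lowest wavelength by the strictness requirement.
#'
#' @param values profile values on `wavelengths`.
#' @param wavelengths nm grid.
#' @param span_nm full window width in nm (100 for RC, 50 for VIP in the
#'   study design).
#' @param mode `"maxima"`, `"minima"`, or `"both"`.
#' @return Data frame: `wavelength_nm`, `value`, `kind` ("max"/"min").
#' @export
find_local_peaks <- function(values, wavelengths, span_nm,
                             mode = c("maxima", "minima", "both")) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop("empty profile")
  if (length(values) != length(wavelengths)) stop("length mismatch")
  half <- span_nm / 2
  if (half <= min(diff(wavelengths))) stop("span must exceed the grid step")
  segs <- grid_segments(wavelengths)
  out <- list()
  for (sg in unique(segs)) {
    cols <- which(segs == sg)
    wl <- wavelengths[cols]; v <- values[cols]
    L <- length(cols)
    if (L < 3) next
    for (i in 2:(L - 1)) {  # segment endpoints excluded
      win <- which(abs(wl - wl[i]) <= half)
      oth <- setdiff(win, i)
      if (mode != "minima" && all(v[i] > v[oth]))
        out[[length(out) + 1]] <- data.frame(wavelength_nm = wl[i],
                                             value = v[i], kind = "max")
      else if (mode != "maxima" && all(v[i] < v[oth]))
        out[[length(out) + 1]] <- data.frame(wavelength_nm = wl[i],
                                             value = v[i], kind = "min")
    }
  }
  if (length(out) == 0)
    return(data.frame(wavelength_nm = numeric(0), value = numeric(0),
                      kind = character(0)))
  do.call(rbind, out)
}

#' Peak positions of an importance profile
#'
#' Convenience wrapper applying the study conventions: RC peaks are local
#' maxima and minima within a 100 nm span; VIP peaks are local maxima
#' within a 50 nm span.
#'
#' @param profile an `importance_profile` from [median_profiles()].
#' @param rc_span_nm,vip_span_nm window widths.
#' @return List with data frames `rc_peaks` and `vip_peaks`.
#' @export
profile_peaks <- function(profile, rc_span_nm = 100, vip_span_nm = 50) {
  list(rc_peaks = find_local_peaks(profile$median_rc, profile$wavelengths,
                                   rc_span_nm, mode = "both"),
       vip_peaks = find_local_peaks(profile$median_vip, profile$wavelengths,
                                    vip_span_nm, mode = "maxima"))
}

#' Match peaks of candidate datasets against a reference peak list
#'
#' A reference peak is matched in a candidate dataset iff some candidate
#' peak lies within that dataset's tolerance (nm) of it. Returns a table
#' with one row per reference peak, one logical column per candidate
#' dataset, and per-dataset match totals.
#'
#' @param reference data frame with a `wavelength_nm` column (e.g. VIP
#'   peaks of the best model).
#' @param candidates named list of peak data frames.
#' @param tolerances named numeric vector of per-dataset tolerances in nm
#'   (e.g. 10 for a 1 nm device, 20 for a 5 nm device).
#' @return A list of class `match_table`: `table` (logical matrix), `totals`
#'   (named column sums), `reference_nm`, `tolerances`.
#' @export
match_peaks <- function(reference, candidates, tolerances) {
  if (any(tolerances <= 0)) stop("tolerances must be positive")
  if (!all(names(candidates) %in% names(tolerances)))
    stop("every candidate dataset needs a tolerance")
  ref_nm <- reference$wavelength_nm
  tab <- matrix(FALSE, length(ref_nm), length(candidates),
                dimnames = list(NULL, names(candidates)))
  for (d in names(candidates)) {
    cand_nm <- candidates[[d]]$wavelength_nm
    if (length(cand_nm) > 0)
      for (i in seq_along(ref_nm))
        tab[i, d] <- min(abs(ref_nm[i] - cand_nm)) <= tolerances[[d]]
  }
  structure(list(table = tab, totals = colSums(tab), reference_nm = ref_nm,
                 tolerances = tolerances),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  df <- data.frame(reference_nm = x$reference_nm, x$table)
  print(df)
  cat("totals:", paste(names(x$totals), x$totals, sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Select wavelengths by VIP threshold
#'
#' The usual variable-selection rule: keep wavelengths whose (median) VIP
#' score is strictly above the threshold (default 1).
#'
#' @param profile an `importance_profile`, or a numeric VIP vector with a
#'   `wavelengths` attribute supplied via `wavelengths`.
#' @param threshold selection threshold.
#' @param wavelengths grid when `profile` is a bare numeric vector.
#' @return Numeric vector of selected wavelengths (nm).
#' @export
vip_selection <- function(profile, threshold = 1, wavelengths = NULL) {
  if (inherits(profile, "importance_profile")) {
    wavelengths <- profile$wavelengths
    v <- profile$median_vip
  } else v <- profile
  wavelengths[v > threshold]
}
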