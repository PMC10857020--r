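# Spectral preprocessing: splice correction, range trimming, robust
# replicate outlier removal, and the four model-building operators
# (Savitzky-Golay derivative, SG + continuum removal, gap-segment
# derivative, multiplicative scatter correction).

# contiguous grid segments: a new segment starts wherever the wavelength
# step jumps above 1.5x the modal step (dead bands are never bridged)
grid_segments <- function(wl) {
  if (length(wl) < 2) return(rep(1L, length(wl)))
  steps <- diff(wl)
  cumsum(c(1L, as.integer(steps > 1.5 * min(steps))))
}

#' Correct inter-sensor reflectance steps
#'
#' Instruments assembled from several internal sensors show additive
#' reflectance steps at the splice wavelengths. Each segment beyond a splice
#' point is additively shifted so that its first value equals the linear
#' extrapolation from the last two points of the preceding (already
#' corrected) segment; the lowest-wavelength segment is the fixed anchor.
#'
#' @param s a [spectrum_set()].
#' @param splice_points nm positions interior to the grid.
#' @return A corrected [spectrum_set()].
#' @export
splice_correct <- function(s, splice_points) {
  wl <- s$wavelengths
  for (sp in splice_points)
    if (sp <= wl[1] || sp >= wl[length(wl)])
      stop("splice point ", sp, " outside the wavelength grid")
  bounds <- c(-Inf, sort(splice_points), Inf)
  seg_of <- cut(wl, bounds, labels = FALSE, right = FALSE)
  refl <- s$reflectance
  for (k in 2:max(seg_of)) {
    prev <- which(seg_of == k - 1)
    cur <- which(seg_of == k)
    i2 <- prev[length(prev)]; i1 <- prev[length(prev) - 1]
    slope <- (refl[, i2] - refl[, i1]) / (wl[i2] - wl[i1])
    extrap <- refl[, i2] + slope * (wl[cur[1]] - wl[i2])
    shift <- extrap - refl[, cur[1]]
    refl[, cur] <- refl[, cur] + shift
  }
  s$reflectance <- refl
  s
}

#' Trim the wavelength range
#'
#' Keeps wavelengths inside `[lo, hi]` (used to restrict both devices to a
#' common 400-2200 nm modelling range and to drop noisy grid ends).
#'
#' @param s a [spectrum_set()].
#' @param lo,hi range limits in nm.
#' @return A trimmed [spectrum_set()].
#' @export
trim_range <- function(s, lo, hi) {
  if (lo >= hi) stop("lo must be < hi")
  keep <- s$wavelengths >= lo & s$wavelengths <= hi
  if (!any(keep)) stop("no wavelengths remain after trimming")
  s$reflectance <- s$reflectance[, keep, drop = FALSE]
  s$wavelengths <- s$wavelengths[keep]
  s
}

# deterministic MCD-style robust location/scatter: coordinatewise
# median/MAD start, then iterated 0.975-chi-square reweighting.  A full
# covariance is only estimable with a comfortable sample-to-dimension
# ratio (n >= 2k + 2); smaller groups keep a diagonal robust scale, and a
# singular full covariance also falls back to the diagonal (with a
# warning from the caller).
robust_center_cov <- function(scores) {
  n <- nrow(scores); k <- ncol(scores)
  ctr <- apply(scores, 2, median)
  scl <- apply(scores, 2, mad)
  scl[scl < 1e-12] <- max(1e-12, 1e-6 * max(scl))
  d2 <- colSums(((t(scores) - ctr) / scl)^2)
  singular <- FALSE
  use_full <- n >= 2 * k + 2
  for (it in 1:3) {
    wgt <- as.numeric(d2 <= qchisq(0.975, k))
    if (sum(wgt) < 2) wgt <- as.numeric(rank(d2, ties.method = "first") <= 2)
    ctr <- colSums(scores * wgt) / sum(wgt)
    xc <- sweep(scores, 2, ctr)
    if (use_full) {
      cv <- crossprod(xc * wgt, xc) / max(sum(wgt) - 1, 1)
      ev <- eigen(cv, symmetric = TRUE)
      if (min(ev$values) < 1e-10 * max(ev$values, 1e-300)) {
        singular <- TRUE
        cv <- diag(pmax(diag(cv), 1e-12), k)
        ev <- eigen(cv, symmetric = TRUE)
      }
      inv <- ev$vectors %*% diag(1 / ev$values, k) %*% t(ev$vectors)
      d2 <- rowSums((xc %*% inv) * xc)
    } else {
      scl <- sqrt(colSums(xc^2 * wgt) / max(sum(wgt) - 1, 1))
      scl[scl < 1e-12] <- max(1e-12, 1e-6 * max(scl))
      d2 <- colSums((t(xc) / scl)^2)
    }
  }
  list(center = ctr, d2 = d2, singular = singular)
}

# adjusted chi-square cutoff (adaptive reweighting): the 0.975 base
# quantile is raised when the empirical distance tail is lighter than
# chi-square, so clean replicate groups lose nothing
adjusted_cutoff <- function(d2, k) {
  n <- length(d2)
  delta <- qchisq(0.975, k)
  ds <- sort(d2)
  gap <- pchisq(ds, k) - (seq_len(n) - 1) / n
  gap[ds < delta] <- -Inf
  alpha_n <- max(0, max(gap))
  acrit <- (0.24 - 0.003 * min(k, 10)) / sqrt(n)
  if (alpha_n <= acrit) return(Inf)
  thr <- ds[min(n, ceiling(n * (1 - alpha_n)))]
  max(delta, thr)
}

#' Remove multivariate replicate outliers
#'
#' Per (sample, device, condition) group: spectra are projected onto
#' principal components retaining at least 99% of the variance (capped at
#' n - 2 components), robust center and covariance are obtained by a
#' deterministic minimum-covariance-determinant-style reweighting, and
#' spectra whose squared robust distance exceeds an adaptively adjusted
#' chi-square quantile (base 0.975) are removed. Groups with fewer than
#' `min_group` spectra pass through untouched and are reported.
#'
#' @param s a [spectrum_set()].
#' @param min_group smallest group size for which distances are defined.
#' @return A list with `spectra` (the cleaned [spectrum_set()]) and
#'   `report` (data frame: group, n, n_removed, skipped, singular).
#' @export
remove_outliers <- function(s, min_group = 4) {
  key <- paste(s$meta$sample_id, s$meta$device, s$meta$condition, sep = "\r")
  groups <- split(seq_len(n_spectra(s)), key)[unique(key)]
  keep <- logical(n_spectra(s))
  rep_rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    n <- length(idx)
    if (n < min_group) {
      keep[idx] <- TRUE
      rep_rows[[gi]] <- data.frame(group = names(groups)[gi], n = n,
                                   n_removed = 0L, skipped = TRUE,
                                   singular = FALSE)
      next
    }
    X <- s$reflectance[idx, , drop = FALSE]
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    evar <- pc$sdev^2
    if (sum(evar) < 1e-24) {
      # all replicates identical: nothing to remove
      keep[idx] <- TRUE
      rep_rows[[gi]] <- data.frame(group = names(groups)[gi], n = n,
                                   n_removed = 0L, skipped = FALSE,
                                   singular = FALSE)
      next
    }
    k <- which(cumsum(evar) / sum(evar) >= 0.99)[1]
    k <- max(1L, min(k, n - 2L))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    rc <- robust_center_cov(scores)
    if (rc$singular)
      warning("singular covariance in group ", names(groups)[gi],
              "; diagonal fallback used")
    cutoff <- adjusted_cutoff(rc$d2, k)
    flag <- rc$d2 > cutoff
    if (all(flag)) flag[] <- FALSE  # never empty a group
    keep[idx] <- !flag
    rep_rows[[gi]] <- data.frame(group = names(groups)[gi], n = n,
                                 n_removed = sum(flag), skipped = FALSE,
                                 singular = rc$singular)
  }
  list(spectra = subset_spectra(s, which(keep)),
       report = do.call(rbind, rep_rows))
}

# Savitzky-Golay convolution weights for the window center, from the
# polynomial least-squares design (signal::sgolay supplies the filter
# matrix; its central row is the symmetric interior filter).  Scaled to a
# derivative per nm for grid step h.
sg_coefficients <- function(window, poly_order, derivative_order, h) {
  Fm <- signal::sgolay(p = poly_order, n = window, m = derivative_order)
  ctr <- (window + 1) / 2
  co <- Fm[ctr, ]
  co / h^derivative_order
}

#' Savitzky-Golay smoothing / derivative
#'
#' Per-segment polynomial convolution filter. Edge points where the window
#' does not fit are dropped, so an 11-point window on a 1 nm 400-2200 nm
#' grid yields 405-2195 nm.
#'
#' @param s a [spectrum_set()].
#' @param window odd window length in points.
#' @param poly_order polynomial order (must be `< window`).
#' @param derivative_order 0 for smoothing, 1 for the first derivative
#'   (per nm), etc.
#' @return A [spectrum_set()] on the reduced grid.
#' @export
savitzky_golay <- function(s, window = 11, poly_order = 2,
                           derivative_order = 1) {
  if (window %% 2 != 1) stop("window must be odd")
  if (poly_order >= window) stop("window must exceed poly_order")
  segs <- grid_segments(s$wavelengths)
  half <- (window - 1) / 2
  out_wl <- numeric(0)
  out <- NULL
  for (sg in unique(segs)) {
    cols <- which(segs == sg)
    if (length(cols) < window)
      stop("segment shorter than the filter window")
    h <- diff(s$wavelengths[cols])
    if (max(h) - min(h) > 1e-8 * mean(h))
      stop("non-uniform grid within a segment")
    co <- sg_coefficients(window, poly_order, derivative_order, mean(h))
    L <- length(cols)
    res <- matrix(0, n_spectra(s), L - window + 1)
    for (j in seq_len(window))
      res <- res + co[j] * s$reflectance[, cols[j:(j + L - window)], drop = FALSE]
    out_wl <- c(out_wl, s$wavelengths[cols[(half + 1):(L - half)]])
    out <- cbind(out, res)
  }
  spectrum_set(out_wl, out, s$meta)
}

# Andrew's monotone-chain upper convex hull over (wavelength, value)
upper_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      # drop b if it lies below the chord a -> i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) >= 0)
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Continuum removal
#'
#' Divides each spectrum by its upper convex hull (piecewise linear over
#' wavelength), isolating absorption features. Output lies in (0, 1] and is
#' exactly 1 at hull support points, including both segment endpoints.
#' Contiguous grid segments are hulled independently.
#'
#' @param s a [spectrum_set()] with strictly positive reflectance.
#' @return A [spectrum_set()] of continuum-removed spectra.
#' @export
continuum_removal <- function(s) {
  if (any(s$reflectance <= 0)) stop("continuum removal requires positive reflectance")
  segs <- grid_segments(s$wavelengths)
  out <- s$reflectance
  for (sg in unique(segs)) {
    cols <- which(segs == sg)
    x <- s$wavelengths[cols]
    for (i in seq_len(n_spectra(s))) {
      y <- s$reflectance[i, cols]
      hi <- upper_hull_idx(x, y)
      cont <- stats::approx(x[hi], y[hi], xout = x)$y
      out[i, cols] <- y / cont
    }
  }
  s$reflectance <- out
  s
}

#' Gap-segment first derivative
#'
#' Noise-robust derivative: the difference between the mean reflectance of a
#' trailing and a leading segment of `s_seg` points, separated by a gap of
#' `w` points centered on the output point, divided by the center-to-center
#' wavelength distance `(w + s_seg) * h`. Points without full support are
#' dropped (w = 11, s = 10 on a 1 nm 400-2200 grid gives 415-2185 nm).
#'
#' @param s a [spectrum_set()].
#' @param w gap width in points (odd).
#' @param s_seg averaging segment length in points.
#' @return A [spectrum_set()] of first derivatives (per nm) on the reduced
#'   grid.
#' @export
gap_segment_derivative <- function(s, w = 11, s_seg = 10) {
  if (w %% 2 != 1) stop("gap width w must be odd")
  if (s_seg < 1) stop("segment length must be >= 1")
  g <- (w - 1) / 2
  reach <- g + s_seg
  segs <- grid_segments(s$wavelengths)
  out_wl <- numeric(0)
  out <- NULL
  for (sg in unique(segs)) {
    cols <- which(segs == sg)
    L <- length(cols)
    if (L < 2 * reach + 1) stop("segment too short for gap + averaging segments")
    h <- mean(diff(s$wavelengths[cols]))
    centers <- (reach + 1):(L - reach)
    lead <- matrix(0, n_spectra(s), length(centers))
    trail <- matrix(0, n_spectra(s), length(centers))
    for (j in seq_len(s_seg)) {
      lead <- lead + s$reflectance[, cols[centers - g - j], drop = FALSE]
      trail <- trail + s$reflectance[, cols[centers + g + j], drop = FALSE]
    }
    d <- (trail - lead) / s_seg / ((w + s_seg) * h)
    out_wl <- c(out_wl, s$wavelengths[cols[centers]])
    out <- cbind(out, d)
  }
  spectrum_set(out_wl, out, s$meta)
}

#' Multiplicative scatter correction
#'
#' Fits each spectrum against a reference by ordinary least squares,
#' `x ~ a + b * reference`, and returns `(x - a) / b`. The reference
#' defaults to the set mean and is attached to the result (attribute
#' `msc_reference`) so new data can be corrected against the same reference.
#'
#' @param s a [spectrum_set()].
#' @param reference reference spectrum on the same grid; `NULL` uses the
#'   column mean of `s`.
#' @return A corrected [spectrum_set()] carrying the reference used.
#' @export
msc <- function(s, reference = NULL) {
  if (is.null(reference)) reference <- colMeans(s$reflectance)
  if (length(reference) != length(s$wavelengths))
    stop("reference must be on the same wavelength grid")
  mr <- mean(reference)
  rc <- reference - mr
  ss <- sum(rc^2)
  out <- s$reflectance
  for (i in seq_len(n_spectra(s))) {
    x <- s$reflectance[i, ]
    b <- sum((x - mean(x)) * rc) / ss
    if (abs(b) < 1e-12)
      stop("degenerate scatter slope for spectrum ", s$meta$sample_id[i])
    a <- mean(x) - b * mr
    out[i, ] <- (x - a) / b
  }
  s$reflectance <- out
  attr(s, "msc_reference") <- reference
  s
}

#' Apply one of the four study preprocessing operators
#'
#' `"SG"`: Savitzky-Golay first derivative (window 11, order 2).
#' `"SGCR"`: Savitzky-Golay smoothing (window 11, order 2) followed by
#' continuum removal. `"gapDer"`: gap-segment first derivative (w = 11,
#' s = 10). `"MSC"`: multiplicative scatter correction against the set mean
#' (or a supplied reference).
#'
#' @param s a [spectrum_set()].
#' @param method one of `"SG"`, `"SGCR"`, `"gapDer"`, `"MSC"`.
#' @param msc_reference optional stored MSC reference for reuse on new data.
#' @return A preprocessed [spectrum_set()].
#' @export
preprocess_spectra <- function(s, method = c("SG", "SGCR", "gapDer", "MSC"),
                               msc_reference = NULL) {
  method <- match.arg(method)
  switch(method,
         SG = savitzky_golay(s, window = 11, poly_order = 2,
                             derivative_order = 1),
         SGCR = continuum_removal(savitzky_golay(s, window = 11,
                                                 poly_order = 2,
                                                 derivative_order = 0)),
         gapDer = gap_segment_derivative(s, w = 11, s_seg = 10),
         MSC = msc(s, reference = msc_reference))
}

#' Full data-preparation pipeline for one device/condition
#'
#' Fixed operator order: splice correction (high-resolution device), range
#' trimming to the common modelling range, robust replicate outlier
#' removal, replicate averaging, then the chosen preprocessing operator.
#'
#' @param s a replicate-level [spectrum_set()].
#' @param method preprocessing operator, see [preprocess_spectra()].
#' @param splice_points nm positions to splice-correct (empty = skip).
#' @param range modelling range in nm, default `c(400, 2200)`.
#' @param msc_reference optional stored MSC reference.
#' @return A per-location averaged, preprocessed [spectrum_set()].
#' @export
prepare_dataset <- function(s, method, splice_points = numeric(0),
                            range = c(400, 2200), msc_reference = NULL) {
  if (length(splice_points) > 0) s <- splice_correct(s, splice_points)
  s <- trim_range(s, range[1], range[2])
  s <- remove_outliers(s)$spectra
  s <- average_replicates(s)
  preprocess_spectra(s, method, msc_reference = msc_reference)
}
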