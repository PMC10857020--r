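#' Fit a PLS1 regression model (NIPALS)
#'
#' Sequential NIPALS extraction on mean-centered (never variance-scaled)
#' predictors and response, with X deflation per component. The model keeps
#' everything the importance analysis needs: normalized weight vectors
#' `W`, x-loadings `P`, scores `T`, y-loadings `q`, the per-component
#' explained sum of squares of y `SS_a = q_a^2 * t_a' t_a`, and cumulative
#' regression coefficients for every component count up to `A`.
#'
#' @param X numeric matrix, samples x wavelengths.
#' @param y numeric response (SOC, g kg-1).
#' @param A number of components; truncated with a warning if it exceeds
#'   the effective rank.
#' @param wavelengths optional wavelength grid stored with the model.
#' @param warn_truncate warn when fewer components than requested can be
#'   extracted (the response deflates to numerical zero first).
#' @return An object of class `plsr_model` with elements `A`, `x_mean`,
#'   `y_mean`, `W`, `P`, `T`, `q`, `SS`, `coefs` (p x A, column a = beta at
#'   a components), `beta` (coefficients at `A` components), `p`,
#'   `wavelengths`.
#' @export
fit_plsr <- function(X, y, A, wavelengths = NULL, warn_truncate = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite entries in X or y")
  if (var(y) == 0) stop("zero-variance response")
  A_req <- as.integer(A)
  if (A_req < 1) stop("A must be >= 1")
  A_cap <- min(A_req, nrow(X) - 1L, ncol(X))
  fit <- cpp_pls_fit(X, y, A_cap)
  if (fit$A < A_req && warn_truncate)
    warning("requested ", A_req, " components; rank allowed ", fit$A)
  structure(list(A = fit$A, x_mean = as.numeric(fit$x_mean),
                 y_mean = fit$y_mean, W = fit$W, P = fit$P, T = fit$T,
                 q = as.numeric(fit$q), SS = as.numeric(fit$SS),
                 coefs = fit$coefs, beta = fit$coefs[, fit$A],
                 p = ncol(X),
                 wavelengths = if (is.null(wavelengths)) seq_len(ncol(X))
                               else as.numeric(wavelengths)),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, %d wavelengths\n", x$A, x$p))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' `yhat = y_mean + (X - x_mean) %*% beta`, optionally at a smaller
#' component count than the model was fitted with.
#'
#' @param object a `plsr_model`.
#' @param newdata matrix on the model's wavelength grid (or a
#'   [spectrum_set()]).
#' @param ncomp component count to predict at (default: the fitted `A`).
#' @param ... unused.
#' @return Numeric vector of predictions (g kg-1).
#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$A, ...) {
  if (inherits(newdata, "spectrum_set")) {
    if (length(newdata$wavelengths) != object$p ||
        max(abs(newdata$wavelengths - object$wavelengths)) > 1e-8)
      stop("wavelength grid mismatch")
    newdata <- newdata$reflectance
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("wavelength grid mismatch")
  if (ncomp < 1 || ncomp > object$A) stop("ncomp out of range")
  beta <- object$coefs[, ncomp]
  drop(object$y_mean + sweep(newdata, 2, object$x_mean) %*% beta)
}

#' Regression coefficients per wavelength
#'
#' The model's coefficients on the original (centered, unscaled)
#' reflectance scale; large magnitudes mark wavelengths that drive the
#' prediction.
#'
#' @param m a `plsr_model`.
#' @param ncomp component count (default the fitted `A`).
#' @return Numeric vector, one coefficient per wavelength.
#' @export
regression_coefficients <- function(m, ncomp = m$A) {
  if (!inherits(m, "plsr_model")) stop("not a plsr_model")
  m$coefs[, ncomp]
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SS_a * (w_aj / ||w_a||)^2 / sum_a SS_a )`,
#' where `SS_a` is the response sum of squares explained by component `a`.
#' Under this convention `sum_j VIP_j^2 = p`.
#'
#' @param m a `plsr_model`.
#' @param ncomp number of components to aggregate over (default `m$A`).
#' @return Numeric vector of VIP scores per wavelength.
#' @export
vip <- function(m, ncomp = m$A) {
  if (!inherits(m, "plsr_model")) stop("not a plsr_model")
  if (ncomp < 1 || ncomp > m$A) stop("ncomp out of range")
  W <- m$W[, seq_len(ncomp), drop = FALSE]
  SS <- m$SS[seq_len(ncomp)]
  if (sum(SS) <= 0) stop("no explained variance")
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")  # ||w_a|| = 1 by construction
  sqrt(m$p * drop(Wn^2 %*% SS) / sum(SS))
}
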