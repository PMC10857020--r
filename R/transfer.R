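# Lab-based correction of field spectra: per-wavelength linear
# transformation (LT), piecewise direct standardization (PDS) and external
# parameter orthogonalization (EPO), plus nested-CV parameter tuning.

align_pair <- function(field, lab) {
  if (length(field$wavelengths) != length(lab$wavelengths) ||
      max(abs(field$wavelengths - lab$wavelengths)) > 1e-8)
    stop("field and lab sets must share a wavelength grid")
  ids <- field$meta$sample_id
  j <- match(ids, lab$meta$sample_id)
  if (anyNA(j)) stop("field and lab sets must cover the same samples")
  list(Xf = field$reflectance, Xl = lab$reflectance[j, , drop = FALSE],
       ids = ids, wavelengths = field$wavelengths)
}

#' Per-wavelength linear transformation
#'
#' For each wavelength j, ordinary least squares of the lab value on the
#' field value across samples: `lab_j ~ a_j + b_j * field_j`. Applying the
#' model maps field spectra toward the lab domain. Wavelengths with zero
#' field variance get `b_j = 0`, `a_j = mean(lab_j)` (with a warning).
#'
#' @param field,lab per-location averaged [spectrum_set()]s on the same
#'   grid covering the same samples.
#' @return A `transfer_model` of kind `"LT"` with per-wavelength `slope`
#'   and `intercept`.
#' @export
fit_lt <- function(field, lab) {
  ap <- align_pair(field, lab)
  mf <- colMeans(ap$Xf); ml <- colMeans(ap$Xl)
  fc <- sweep(ap$Xf, 2, mf); lc <- sweep(ap$Xl, 2, ml)
  vf <- colSums(fc^2)
  b <- numeric(length(vf))
  ok <- vf > 1e-24
  if (!all(ok)) warning("zero field variance at ", sum(!ok), " wavelengths")
  b[ok] <- colSums(fc * lc)[ok] / vf[ok]
  a <- ml - b * mf
  structure(list(kind = "LT", slope = b, intercept = a,
                 wavelengths = ap$wavelengths),
            class = "transfer_model")
}

#' Piecewise direct standardization
#'
#' For each lab wavelength i, a local PLS model with `ncomp` components
#' maps the field window `[i - w, i + w]` (clipped at grid-segment and dead
#' band boundaries) onto `lab_i`. The coefficients form a banded transform
#' matrix: entries outside the band are exactly zero.
#'
#' @param field,lab paired per-location averaged [spectrum_set()]s.
#' @param w window half-width in grid points.
#' @param ncomp local PLS component count (clipped where the window has
#'   fewer points).
#' @return A `transfer_model` of kind `"PDS"` with the band matrix `band`
#'   (p x (2w+1)), `intercept`, `w` and `ncomp`.
#' @export
fit_pds <- function(field, lab, w, ncomp) {
  if (w < 0) stop("window half-width must be >= 0")
  if (ncomp < 1) stop("ncomp must be >= 1")
  ap <- align_pair(field, lab)
  segs <- grid_segments(ap$wavelengths)
  fit <- cpp_pds_fit(ap$Xf, ap$Xl, as.integer(segs), as.integer(w),
                     as.integer(ncomp))
  structure(list(kind = "PDS", band = fit$coefs[, , ncomp],
                 intercept = fit$intercepts[, ncomp], w = w, ncomp = ncomp,
                 wavelengths = ap$wavelengths),
            class = "transfer_model")
}

#' External parameter orthogonalization
#'
#' The paired per-location lab-minus-field difference matrix `D` is column
#' centered; its first `c` right singular vectors `V` span the disturbance
#' subspace (moisture and other field effects). Spectra are corrected by
#' projection onto the orthogonal complement, `P = I - V V'`.
#'
#' @param field,lab paired per-location averaged [spectrum_set()]s.
#' @param c number of disturbance components to remove.
#' @return A `transfer_model` of kind `"EPO"` holding the orthonormal basis
#'   `V` (p x c).
#' @export
fit_epo <- function(field, lab, c) {
  if (c < 1) stop("c must be >= 1")
  ap <- align_pair(field, lab)
  D <- ap$Xl - ap$Xf
  D <- sweep(D, 2, colMeans(D))
  sv <- svd(D)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  if (c > r) {
    warning("c = ", c, " exceeds rank(D) = ", r, "; truncated")
    c <- r
  }
  structure(list(kind = "EPO", V = sv$v[, seq_len(c), drop = FALSE], c = c,
                 wavelengths = ap$wavelengths),
            class = "transfer_model")
}

#' The explicit EPO projection matrix `I - V V'`
#'
#' Symmetric, idempotent, rank `p - c`. Materialized on demand (the model
#' stores only `V`).
#'
#' @param m a `transfer_model` of kind `"EPO"`.
#' @return A p x p projection matrix.
#' @export
epo_projection <- function(m) {
  stopifnot(m$kind == "EPO")
  diag(nrow(m$V)) - tcrossprod(m$V)
}

#' Apply a transfer model to spectra
#'
#' @param m a `transfer_model` (LT, PDS or EPO).
#' @param x a [spectrum_set()] or a matrix on the model's grid.
#' @return Corrected spectra, same type as the input.
#' @export
apply_transfer <- function(m, x) {
  is_set <- inherits(x, "spectrum_set")
  X <- if (is_set) x$reflectance else as.matrix(x)
  if (ncol(X) != length(m$wavelengths)) stop("wavelength grid mismatch")
  out <- switch(m$kind,
                LT = sweep(sweep(X, 2, m$slope, "*"), 2, m$intercept, "+"),
                PDS = cpp_pds_apply(X, m$band, m$intercept, as.integer(m$w)),
                EPO = X - tcrossprod(X %*% m$V, m$V),
                stop("unknown transfer kind"))
  if (is_set) { x$reflectance <- out; x } else out
}

#' @export
print.transfer_model <- function(x, ...) {
  cat("<transfer_model>", x$kind,
      switch(x$kind,
             LT = "",
             PDS = sprintf("(w = %d, ncomp = %d)", x$w, x$ncomp),
             EPO = sprintf("(c = %d)", x$c)), "\n")
  invisible(x)
}

fit_transfer <- function(kind, field, lab, par) {
  switch(kind,
         LT = fit_lt(field, lab),
         PDS = fit_pds(field, lab, par$w, par$ncomp),
         EPO = fit_epo(field, lab, par$c))
}

#' Tune a field-data correction inside the nested cross-validation
#'
#' Uses exactly the same outer/inner fold subdivisions as [nested_cv()].
#' Per repetition and outer fold the transfer model and the downstream PLS
#' model are fit on outer-training samples only — and, during tuning, refit
#' on inner-training folds so no held-out sample of either level leaks into
#' the transfer fit. The tuning grid (PDS: ncomp 1-10 x window 1-20; EPO:
#' c 1-10; LT: no transfer grid) is scored by the pooled inner-CV RMSE of
#' the corrected-field PLS model, ties going to the smallest ncomp, then
#' the smallest window. Held-out predictions use the outer-test field
#' spectra corrected by the outer-training transfer model.
#'
#' @param field,lab paired per-location averaged (preprocessed)
#'   [spectrum_set()]s.
#' @param samples a [sample_table()].
#' @param method `"LT"`, `"PDS"` or `"EPO"`.
#' @param scheme a [cv_scheme()].
#' @param A_max largest downstream PLS component count.
#' @param pds_ncomp,pds_w,epo_c tuning grids.
#' @return A list with `predictions` (held-out predictions as in
#'   [nested_cv()] plus selected-parameter columns), `models`, `selection`
#'   (one row per repetition x fold) and `params_mode` (most frequent
#'   selection).
#' @export
tune_transfer <- function(field, lab, samples, method = c("LT", "PDS", "EPO"),
                          scheme = cv_scheme(), A_max = 20,
                          pds_ncomp = 1:10, pds_w = 1:20, epo_c = 1:10) {
  method <- match.arg(method)
  ap <- align_pair(field, lab)
  j <- match(ap$ids, samples$sample_id)
  if (anyNA(j)) stop("samples table must cover all spectra")
  samples <- samples[j, ]
  y <- samples$soc
  n <- length(y)
  groups <- build_spatial_groups(samples, scheme$min_separation)
  segs <- as.integer(grid_segments(ap$wavelengths))

  grid <- switch(method,
                 LT = data.frame(dummy = 1),
                 PDS = expand.grid(ncomp = pds_ncomp, w = pds_w),
                 EPO = data.frame(c = epo_c))
  if (nrow(grid) == 0) stop("empty tuning grid")
  # tie order: smallest ncomp/c first, then smallest window
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]

  preds <- list(); models <- list(); sel_rows <- list()
  for (r in seq_len(scheme$repetitions)) {
    fold <- assign_folds(groups, y, scheme$k_outer,
                         subseed(scheme$seed, 100L + r))
    for (f in seq_len(scheme$k_outer)) {
      tr <- which(fold != f); te <- which(fold == f)
      seed_in <- subseed(scheme$seed, 1000L + r * 10L + f)
      Xf_tr <- ap$Xf[tr, , drop = FALSE]
      Xl_tr <- ap$Xl[tr, , drop = FALSE]

      # inner folds: identical subdivisions to nested_cv (same seed), with
      # the transfer refit on inner-training samples inside every fold so
      # the inner score is leakage-free for the transfer too
      gtr <- match(groups[tr], unique(groups[tr]))
      k_in <- min(scheme$k_inner, length(unique(gtr)))
      infold <- assign_folds(gtr, y[tr], k_in, seed_in)
      A_cap <- min(A_max, length(tr) - 2L, ncol(Xf_tr))

      best <- NULL
      take <- function(cand) {
        if (is.null(best) || cand$rmse < best$rmse - 1e-12) best <<- cand
      }
      if (method == "PDS") {
        cube <- cpp_pds_tune(Xf_tr, Xl_tr, y[tr], segs, as.integer(infold),
                             as.integer(sort(unique(pds_w))),
                             as.integer(max(pds_ncomp)), as.integer(A_cap))
        ws <- sort(unique(pds_w))
        for (nc in sort(unique(pds_ncomp))) for (w_i in seq_along(ws)) {
          curve <- cube[w_i, nc, ]
          take(list(par = list(w = ws[w_i], ncomp = nc),
                    plsr_ncomp = which.min(curve), rmse = min(curve)))
        }
      } else if (method == "EPO") {
        sses <- matrix(0, length(epo_c), A_cap)
        cnt <- 0
        for (fi in seq_len(k_in)) {
          itr <- tr[infold != fi]; ite <- tr[infold == fi]
          cnt <- cnt + length(ite)
          D <- ap$Xl[itr, , drop = FALSE] - ap$Xf[itr, , drop = FALSE]
          D <- sweep(D, 2, colMeans(D))
          sv <- svd(D)
          rk <- sum(sv$d > 1e-10 * sv$d[1])
          for (ci in seq_along(epo_c)) {
            cc <- min(epo_c[ci], rk)
            V <- sv$v[, seq_len(cc), drop = FALSE]
            Xtr_c <- ap$Xf[itr, , drop = FALSE]
            Xtr_c <- Xtr_c - tcrossprod(Xtr_c %*% V, V)
            Xte_c <- ap$Xf[ite, , drop = FALSE]
            Xte_c <- Xte_c - tcrossprod(Xte_c %*% V, V)
            sses[ci, ] <- sses[ci, ] +
              score_curve(Xtr_c, y[itr], Xte_c, y[ite], A_cap)
          }
        }
        for (ci in seq_along(epo_c)) {
          curve <- sqrt(sses[ci, ] / cnt)
          take(list(par = list(c = epo_c[ci]),
                    plsr_ncomp = which.min(curve), rmse = min(curve)))
        }
      } else {
        sse <- numeric(A_cap); cnt <- 0
        for (fi in seq_len(k_in)) {
          itr <- tr[infold != fi]; ite <- tr[infold == fi]
          cnt <- cnt + length(ite)
          tm_i <- lt_from_matrices(ap$Xf[itr, , drop = FALSE],
                                   ap$Xl[itr, , drop = FALSE],
                                   ap$wavelengths)
          sse <- sse + score_curve(
            apply_transfer(tm_i, ap$Xf[itr, , drop = FALSE]), y[itr],
            apply_transfer(tm_i, ap$Xf[ite, , drop = FALSE]), y[ite], A_cap)
        }
        curve <- sqrt(sse / cnt)
        best <- list(par = list(), plsr_ncomp = which.min(curve),
                     rmse = min(curve))
      }

      tm <- switch(method,
                   LT = lt_from_matrices(Xf_tr, Xl_tr, ap$wavelengths),
                   PDS = {
                     fit <- cpp_pds_fit(Xf_tr, Xl_tr, segs,
                                        as.integer(best$par$w),
                                        as.integer(best$par$ncomp))
                     structure(list(kind = "PDS",
                                    band = fit$coefs[, , best$par$ncomp],
                                    intercept = fit$intercepts[, best$par$ncomp],
                                    w = best$par$w, ncomp = best$par$ncomp,
                                    wavelengths = ap$wavelengths),
                               class = "transfer_model")
                   },
                   EPO = {
                     D <- Xl_tr - Xf_tr
                     D <- sweep(D, 2, colMeans(D))
                     sv <- svd(D)
                     rk <- sum(sv$d > 1e-10 * sv$d[1])
                     cc <- min(best$par$c, rk)
                     structure(list(kind = "EPO",
                                    V = sv$v[, seq_len(cc), drop = FALSE],
                                    c = cc, wavelengths = ap$wavelengths),
                               class = "transfer_model")
                   })
      Xc_tr <- apply_transfer(tm, Xf_tr)
      Xc_te <- apply_transfer(tm, ap$Xf[te, , drop = FALSE])
      m <- fit_plsr(Xc_tr, y[tr], best$plsr_ncomp,
                    wavelengths = ap$wavelengths)
      yhat <- predict(m, Xc_te)
      row <- data.frame(repetition = r, fold = f,
                        sample_id = samples$sample_id[te],
                        observed = y[te], predicted = yhat,
                        ncomp = m$A, stringsAsFactors = FALSE)
      sel <- data.frame(repetition = r, fold = f, method = method,
                        plsr_ncomp = best$plsr_ncomp,
                        inner_rmse = best$rmse)
      if (method == "PDS") { sel$pds_w <- best$par$w; sel$pds_ncomp <- best$par$ncomp }
      if (method == "EPO") sel$epo_c <- tm$c
      preds[[length(preds) + 1]] <- row
      sel_rows[[length(sel_rows) + 1]] <- sel
      models[[length(models) + 1]] <- m
    }
  }
  selection <- do.call(rbind, sel_rows)
  mode_of <- function(v) as.numeric(names(sort(table(v), decreasing = TRUE))[1])
  params_mode <- switch(method,
                        LT = data.frame(method = "LT"),
                        PDS = data.frame(method = "PDS",
                                         pds_ncomp = mode_of(selection$pds_ncomp),
                                         pds_w = mode_of(selection$pds_w)),
                        EPO = data.frame(method = "EPO",
                                         epo_c = mode_of(selection$epo_c)))
  list(predictions = do.call(rbind, preds), models = models,
       selection = selection, params_mode = params_mode)
}

# held-out SSE at every component count for one train/test split
score_curve <- function(Xtr, ytr, Xte, yte, A) {
  fit <- cpp_pls_fit(Xtr, ytr, min(A, length(ytr) - 1L))
  Xc <- sweep(Xte, 2, as.numeric(fit$x_mean))
  pred <- fit$y_mean + Xc %*% fit$coefs
  res2 <- (pred - yte)^2
  out <- numeric(A)
  a_used <- ncol(pred)
  out[seq_len(a_used)] <- colSums(res2)
  if (a_used < A) out[(a_used + 1):A] <- sum(res2[, a_used])
  out
}

lt_from_matrices <- function(Xf, Xl, wavelengths) {
  mf <- colMeans(Xf); ml <- colMeans(Xl)
  fc <- sweep(Xf, 2, mf); lc <- sweep(Xl, 2, ml)
  vf <- colSums(fc^2)
  b <- numeric(length(vf))
  ok <- vf > 1e-24
  b[ok] <- colSums(fc * lc)[ok] / vf[ok]
  a <- ml - b * mf
  structure(list(kind = "LT", slope = b, intercept = a,
                 wavelengths = wavelengths),
            class = "transfer_model")
}
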