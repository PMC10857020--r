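#' Cross-validation scheme
#'
#' Stratified, spatially grouped k-fold nested cross-validation: samples
#' closer than `min_separation` always share a fold (to avoid spatial
#' leakage between training and test data), folds are balanced on SOC, and
#' the outer loop is repeated `repetitions` times, giving
#' `k_outer * repetitions` models per dataset (25 at the defaults).
#'
#' @param k_outer outer folds (evaluation).
#' @param k_inner inner folds (hyperparameter tuning).
#' @param repetitions outer-loop repetitions.
#' @param min_separation metres; pairs within this distance share a fold.
#' @param seed integer seed; fold subdivisions are a function of
#'   (seed, sample table) only, so every dataset variant shares identical
#'   splits.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(k_outer = 5, k_inner = 5, repetitions = 5,
                      min_separation = 8, seed = 1L) {
  structure(list(k_outer = k_outer, k_inner = k_inner,
                 repetitions = repetitions,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Group samples by spatial proximity
#'
#' Single-linkage connected components of the graph joining sample pairs
#' whose planar Euclidean distance is at most `min_separation`; each
#' component is an indivisible unit for fold assignment.
#'
#' @param samples a [sample_table()].
#' @param min_separation distance threshold in metres (inclusive).
#' @return Integer group label per sample.
#' @export
build_spatial_groups <- function(samples, min_separation = 8) {
  n <- nrow(samples)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- as.matrix(dist(samples[, c("x_m", "y_m")]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (d[i, j] <= min_separation) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Assign spatial groups to stratified folds
#'
#' Groups are sorted by group-mean SOC and dealt into `k` folds in blocks
#' of `k` consecutive groups, with a seeded random permutation of fold
#' labels within each block (a randomized round-robin). This balances the
#' SOC distribution across folds while leaving the partition random.
#'
#' @param groups integer group label per sample (see
#'   [build_spatial_groups()]).
#' @param soc per-sample SOC values.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold label (1..k) per sample.
#' @export
assign_folds <- function(groups, soc, k, seed) {
  gids <- unique(groups)
  if (length(gids) < k) stop("fewer spatial groups than folds")
  if (k == 1) return(rep(1L, length(groups)))
  gmean <- vapply(gids, function(g) mean(soc[groups == g]), 0)
  ord <- gids[order(gmean)]
  set.seed(seed)
  fold_of_group <- integer(max(gids))
  i <- 1
  while (i <= length(ord)) {
    block <- ord[i:min(i + k - 1, length(ord))]
    fold_of_group[block] <- sample(k, length(block))
    i <- i + k
  }
  fold_of_group[groups]
}

#' Nested cross-validation for PLS regression
#'
#' For each repetition and outer fold: an inner cross-validation on the
#' outer-training samples selects the component count minimizing pooled
#' inner RMSE (ties go to the smallest count), the model is refit on the
#' full outer-training set at that count, and held-out predictions are
#' recorded. Fold subdivisions derive only from the sample table and the
#' scheme seed.
#'
#' @param X numeric matrix of predictors, rows aligned with `samples`.
#' @param samples a [sample_table()] (provides SOC and coordinates).
#' @param scheme a [cv_scheme()].
#' @param A_max largest component count in the tuning grid.
#' @param wavelengths optional grid stored with each model.
#' @return A list with `predictions` (data frame: repetition, fold,
#'   sample_id, observed, predicted, ncomp), `models` (one `plsr_model` per
#'   repetition x outer fold), `folds` (n x repetitions matrix of outer
#'   fold labels), and `groups`.
#' @export
nested_cv <- function(X, samples, scheme = cv_scheme(), A_max = 20,
                      wavelengths = NULL) {
  X <- as.matrix(X)
  y <- samples$soc
  n <- nrow(X)
  if (n != nrow(samples)) stop("X rows must align with the sample table")
  groups <- build_spatial_groups(samples, scheme$min_separation)
  folds <- matrix(0L, n, scheme$repetitions)
  preds <- list()
  models <- list()
  for (r in seq_len(scheme$repetitions)) {
    fold <- assign_folds(groups, y, scheme$k_outer,
                         subseed(scheme$seed, 100L + r))
    folds[, r] <- fold
    for (f in seq_len(scheme$k_outer)) {
      tr <- which(fold != f); te <- which(fold == f)
      ncomp <- tune_ncomp(X[tr, , drop = FALSE], y[tr], groups[tr],
                          scheme, A_max,
                          subseed(scheme$seed, 1000L + r * 10L + f))
      m <- fit_plsr(X[tr, , drop = FALSE], y[tr], ncomp,
                    wavelengths = wavelengths)
      yhat <- predict(m, X[te, , drop = FALSE])
      preds[[length(preds) + 1]] <- data.frame(
        repetition = r, fold = f, sample_id = samples$sample_id[te],
        observed = y[te], predicted = yhat, ncomp = m$A,
        stringsAsFactors = FALSE)
      models[[length(models) + 1]] <- m
    }
  }
  list(predictions = do.call(rbind, preds), models = models, folds = folds,
       groups = groups)
}

# inner CV: one A_max fit per inner fold scores every component count at
# once via the cumulative coefficient matrix; returns the pooled RMSE per
# component count
inner_rmse_curve <- function(Xtr, ytr, gtr, scheme, A_max, seed) {
  gtr_local <- match(gtr, unique(gtr))
  k_in <- min(scheme$k_inner, length(unique(gtr_local)))
  infold <- assign_folds(gtr_local, ytr, k_in, seed)
  if (min(table(infold)) < 1 || length(ytr) - max(table(infold)) < 2)
    stop("inner fold with fewer than 2 training samples")
  A_cap <- min(A_max, length(ytr) - 2L, ncol(Xtr))
  as.numeric(cpp_inner_rmse(Xtr, ytr, as.integer(infold), A_cap))
}

tune_ncomp <- function(Xtr, ytr, gtr, scheme, A_max, seed) {
  which.min(inner_rmse_curve(Xtr, ytr, gtr, scheme, A_max, seed))  # ties -> smallest
}
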