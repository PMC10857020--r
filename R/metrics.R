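#' Model performance metrics
#'
#' Computes RMSE, R-squared, ratio of performance to deviation (RPD) and
#' Lin's concordance correlation coefficient (CCC) for held-out
#' predictions. R-squared is `1 - SSE/SST` about the observed mean (it can
#' be negative on held-out data). RPD uses the n-1 denominator standard
#' deviation of the observations, so `rpd * rmse = sd(observed)` exactly.
#' CCC uses n-denominator moments. A perfect fit reports `rpd = Inf` with
#' the `perfect` flag set.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return A one-row data frame: `rmse` (g kg-1), `r2`, `rpd`, `ccc`, `n`,
#'   `perfect`.
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  n <- length(observed)
  if (n < 2) stop("need at least 2 observations")
  if (var(observed) == 0) stop("zero observed variance")
  err <- observed - predicted
  rmse <- sqrt(mean(err^2))
  sst <- sum((observed - mean(observed))^2)
  r2 <- 1 - sum(err^2) / sst
  perfect <- rmse == 0
  rpd <- if (perfect) Inf else sd(observed) / rmse
  mo <- mean(observed); mp <- mean(predicted)
  vo <- mean((observed - mo)^2); vp <- mean((predicted - mp)^2)
  cv <- mean((observed - mo) * (predicted - mp))
  ccc <- 2 * cv / (vo + vp + (mo - mp)^2)
  data.frame(rmse = rmse, r2 = r2, rpd = rpd, ccc = ccc, n = n,
             perfect = perfect)
}

#' Summarize cross-validation predictions per repetition
#'
#' Pools the held-out predictions of all outer folds within each
#' repetition, computes one set of metrics per repetition (the values shown
#' as boxplots in the study design), and reports the median and IQR of each
#' metric across repetitions.
#'
#' @param cv_predictions data frame with columns `repetition`, `observed`,
#'   `predicted` (the output of [nested_cv()]).
#' @return A list with `per_repetition` (one metrics row per repetition)
#'   and `summary` (median and IQR per metric).
#' @export
summarize_cv <- function(cv_predictions) {
  reps <- sort(unique(cv_predictions$repetition))
  if (length(reps) == 0) stop("no repetitions present")
  per_rep <- do.call(rbind, lapply(reps, function(r) {
    sub <- cv_predictions[cv_predictions$repetition == r, ]
    cbind(repetition = r, compute_metrics(sub$observed, sub$predicted))
  }))
  met <- c("rmse", "r2", "rpd", "ccc")
  summ <- data.frame(
    metric = met,
    median = vapply(met, function(m) median(per_rep[[m]]), 0),
    iqr = vapply(met, function(m) stats::IQR(per_rep[[m]]), 0))
  rownames(summ) <- NULL
  list(per_repetition = per_rep, summary = summ)
}
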