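fit_toy_models <- function(k = 3, seed = 1) {
  set.seed(seed)
  wl <- seq(400, 600, by = 5)
  lapply(1:k, function(i) {
    X <- matrix(rnorm(20 * length(wl)), 20)
    y <- drop(X[, 10]) + rnorm(20, 0, 0.1)
    fit_plsr(X, y, 3, wavelengths = wl)
  })
}

test_that("median profiles aggregate the per-model RC and VIP", {
  ms <- fit_toy_models(5)
  pr <- median_profiles(ms)
  rc <- vapply(ms, regression_coefficients, numeric(41))
  vp <- vapply(ms, vip, numeric(41))
  for (j in c(1, 10, 41)) {
    expect_equal(pr$median_rc[j], sort(rc[j, ])[3])   # sort-based oracle
    expect_equal(pr$median_vip[j], sort(vp[j, ])[3])
  }
  # identical models: the median equals each model
  one <- fit_toy_models(1)
  pr1 <- median_profiles(rep(one, 5))
  expect_equal(pr1$median_rc, regression_coefficients(one[[1]]))

  bad <- fit_toy_models(1, seed = 2)
  bad[[1]]$wavelengths <- bad[[1]]$wavelengths + 1
  expect_error(median_profiles(c(one, bad)), "grid")
})

test_that("local peak detection finds strict extrema within the span window", {
  wl <- seq(400, 800, by = 2)
  bump <- exp(-(wl - 600)^2 / (2 * 20^2))
  pk <- find_local_peaks(bump, wl, span_nm = 50, mode = "maxima")
  expect_equal(nrow(pk), 1)
  expect_equal(pk$wavelength_nm, 600)

  # monotone profiles have no interior peaks
  expect_equal(nrow(find_local_peaks(seq_along(wl), wl, 50, "both")), 0)

  # brute-force window-scan oracle on random profiles
  set.seed(14)
  for (trial in 1:50) {
    v <- rnorm(80)
    wlr <- seq(400, 400 + 79 * 5, by = 5)
    got <- find_local_peaks(v, wlr, span_nm = 40, mode = "both")
    expected <- list()
    for (i in 2:79) {
      win <- which(abs(wlr - wlr[i]) <= 20 & seq_along(wlr) != i)
      if (all(v[i] > v[win]))
        expected[[length(expected) + 1]] <- c(wlr[i], "max")
      else if (all(v[i] < v[win]))
        expected[[length(expected) + 1]] <- c(wlr[i], "min")
    }
    expect_equal(nrow(got), length(expected))
    if (length(expected))
      expect_equal(got$wavelength_nm, as.numeric(vapply(expected, `[`, "", 1)))
  }

  expect_error(find_local_peaks(numeric(0), numeric(0), 50), "empty")
  expect_error(find_local_peaks(bump, wl, span_nm = 1), "span")
})

test_that("peaks are never detected across a dead band", {
  wl <- c(seq(400, 500, by = 2), seq(600, 700, by = 2))
  v <- c(seq_len(51), rev(seq_len(51)))  # rises to the gap, falls after
  pk <- find_local_peaks(v, wl, span_nm = 30, mode = "maxima")
  expect_equal(nrow(pk), 0)  # each segment is monotone
})

test_that("peak matching equals a brute-force tolerance scan and is monotone", {
  set.seed(15)
  for (trial in 1:50) {
    ref <- data.frame(wavelength_nm = sort(runif(8, 400, 2200)))
    cands <- list(a = data.frame(wavelength_nm = sort(runif(6, 400, 2200))),
                  b = data.frame(wavelength_nm = sort(runif(4, 400, 2200))))
    tol <- c(a = 10, b = 20)
    mt <- match_peaks(ref, cands, tol)
    for (d in c("a", "b")) for (i in seq_len(nrow(ref))) {
      brute <- any(abs(ref$wavelength_nm[i] - cands[[d]]$wavelength_nm) <= tol[[d]])
      expect_equal(unname(mt$table[i, d]), brute)
    }
    expect_equal(unname(mt$totals), unname(colSums(mt$table)))
    # totals monotone non-decreasing in tolerance
    mt2 <- match_peaks(ref, cands, tol * 3)
    expect_true(all(mt2$totals >= mt$totals))
  }

  # exact-list match and boundary behavior
  ref <- data.frame(wavelength_nm = c(500, 600))
  self <- match_peaks(ref, list(x = ref), c(x = 10))
  expect_equal(unname(self$totals), 2)
  empty <- match_peaks(ref, list(x = data.frame(wavelength_nm = numeric(0))),
                       c(x = 10))
  expect_equal(unname(empty$totals), 0)
  off <- data.frame(wavelength_nm = c(501, 601))
  expect_equal(unname(match_peaks(ref, list(x = off), c(x = 0.5))$totals), 0)
  expect_equal(unname(match_peaks(ref, list(x = off), c(x = 1))$totals), 2)
  expect_error(match_peaks(ref, list(x = off), c(x = -1)), "positive")
})

test_that("VIP selection keeps wavelengths strictly above the threshold", {
  wl <- c(500, 510, 520)
  pr <- structure(list(wavelengths = wl, median_rc = rep(0, 3),
                       median_vip = c(1.5, 0.2, 1.1)),
                  class = "importance_profile")
  expect_equal(vip_selection(pr), c(500, 520))
  expect_equal(vip_selection(c(1.5, 0.2, 1.1), wavelengths = wl),
               c(500, 520))
  # all-equal-weight single-component model: VIP all exactly 1, none kept
  t_score <- rnorm(12)
  m <- fit_plsr(outer(t_score, rep(1, 5)), t_score, 1, wavelengths = 1:5)
  expect_length(vip_selection(vip(m), wavelengths = 1:5), 0)
})
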