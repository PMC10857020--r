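#' Spectral data container
#'
#' A `spectrum_set` holds a set of reflectance spectra on a common strictly
#' increasing wavelength grid, with one metadata row per spectrum: sample id,
#' device (`"highres"` or `"lowres"`), condition (`"lab"` or `"field"`),
#' replicate id and planar coordinates in metres.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly increasing.
#' @param reflectance numeric matrix, one row per spectrum, one column per
#'   wavelength. Reflectance in `[0, 1]` for raw spectra; derivative units
#'   after preprocessing.
#' @param meta data frame with one row per spectrum. Recognised columns:
#'   `sample_id`, `device`, `condition`, `replicate_id`, `x_m`, `y_m`.
#'   Missing columns are filled with defaults.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavelengths, reflectance, meta = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (is.null(dim(reflectance))) reflectance <- matrix(reflectance, nrow = 1)
  reflectance <- as.matrix(reflectance)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing with no duplicates")
  if (ncol(reflectance) != length(wavelengths))
    stop("reflectance has ", ncol(reflectance), " columns but there are ",
         length(wavelengths), " wavelengths")
  n <- nrow(reflectance)
  if (is.null(meta)) meta <- data.frame(sample_id = as.character(seq_len(n)))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    stop("metadata has ", nrow(meta), " rows but there are ", n, " spectra")
  if (is.null(meta$sample_id)) meta$sample_id <- as.character(seq_len(n))
  meta$sample_id <- as.character(meta$sample_id)
  if (is.null(meta$device)) meta$device <- "highres"
  if (is.null(meta$condition)) meta$condition <- "lab"
  if (is.null(meta$replicate_id)) meta$replicate_id <- as.character(seq_len(n))
  meta$replicate_id <- as.character(meta$replicate_id)
  if (is.null(meta$x_m)) meta$x_m <- NA_real_
  if (is.null(meta$y_m)) meta$y_m <- NA_real_
  key <- paste(meta$sample_id, meta$replicate_id, meta$device, meta$condition)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, replicate_id) within one device/condition")
  dimnames(reflectance) <- NULL
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d wavelengths (%.0f-%.0f nm)\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  cat("  devices:   ", paste(unique(x$meta$device), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$reflectance)

n_spectra <- function(s) nrow(s$reflectance)

subset_spectra <- function(s, rows) {
  spectrum_set(s$wavelengths, s$reflectance[rows, , drop = FALSE],
               s$meta[rows, , drop = FALSE])
}

#' Sample table
#'
#' Per-location ground truth: SOC in g per kg of dry soil and planar
#' coordinates in metres.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param soc numeric, SOC in g kg-1, strictly positive.
#' @param x_m,y_m planar coordinates in metres.
#' @return A data frame of class `sample_table`.
#' @export
sample_table <- function(sample_id, soc, x_m, y_m) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_id must be unique")
  if (any(!is.finite(soc)) || any(soc <= 0)) stop("soc must be positive")
  structure(data.frame(sample_id = sample_id, soc = as.numeric(soc),
                       x_m = as.numeric(x_m), y_m = as.numeric(y_m),
                       stringsAsFactors = FALSE),
            class = c("sample_table", "data.frame"))
}

#' Read spectra from CSV
#'
#' Two dialects are supported. `"wide"`: first column is a spectrum id of
#' the form `sample:replicate` (or a bare sample id), remaining column names
#' are wavelengths in nm. `"long"`: columns `id`, `x_m`, `y_m`,
#' `wavelength_nm`, `reflectance`. Rows may appear in any order.
#'
#' @param path file path.
#' @param dialect `"wide"` or `"long"`.
#' @param device,condition metadata labels applied to all spectra read.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, dialect = c("wide", "long"),
                         device = "highres", condition = "lab") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "wide") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    wl <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(wl)) stop("non-numeric wavelength in header")
    if (anyDuplicated(wl)) stop("duplicated wavelength in header")
    if (any(diff(wl) <= 0)) {
      o <- order(wl)
      wl <- wl[o]
      df <- df[, c(1L, 1L + o)]
      if (any(diff(wl) <= 0)) stop("non-monotone wavelength header")
    }
    ids <- as.character(df[[1]])
    parts <- strsplit(ids, ":", fixed = TRUE)
    meta <- data.frame(
      sample_id = vapply(parts, `[`, "", 1),
      replicate_id = vapply(parts, function(p) if (length(p) > 1) p[2] else "1", ""),
      device = device, condition = condition, stringsAsFactors = FALSE)
    refl <- as.matrix(df[, -1, drop = FALSE])
    mode(refl) <- "numeric"
    spectrum_set(wl, refl, meta)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x_m", "y_m", "wavelength_nm", "reflectance")
    if (!all(need %in% names(df)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "))
    df <- df[order(df$id, df$wavelength_nm), ]
    wl <- sort(unique(df$wavelength_nm))
    if (anyDuplicated(wl)) stop("duplicated wavelength")
    ids <- unique(df$id)
    refl <- matrix(NA_real_, length(ids), length(wl))
    xy <- matrix(NA_real_, length(ids), 2)
    for (i in seq_along(ids)) {
      sub <- df[df$id == ids[i], ]
      if (nrow(sub) != length(wl)) stop("ragged rows for id ", ids[i])
      refl[i, ] <- sub$reflectance[match(wl, sub$wavelength_nm)]
      xy[i, ] <- c(sub$x_m[1], sub$y_m[1])
    }
    parts <- strsplit(as.character(ids), ":", fixed = TRUE)
    meta <- data.frame(
      sample_id = vapply(parts, `[`, "", 1),
      replicate_id = vapply(parts, function(p) if (length(p) > 1) p[2] else "1", ""),
      device = device, condition = condition,
      x_m = xy[, 1], y_m = xy[, 2], stringsAsFactors = FALSE)
    spectrum_set(wl, refl, meta)
  }
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]. Floats are serialized with 9 significant
#' digits (below sensor noise, above round-trip error).
#'
#' @param s a [spectrum_set()].
#' @param path output file path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  id <- paste(s$meta$sample_id, s$meta$replicate_id, sep = ":")
  if (dialect == "wide") {
    df <- data.frame(id = id, signif(s$reflectance, 9), check.names = FALSE)
    names(df) <- c("id", format(s$wavelengths, trim = TRUE, digits = 9))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    n <- nrow(s$reflectance); p <- length(s$wavelengths)
    df <- data.frame(
      id = rep(id, each = p),
      x_m = rep(s$meta$x_m, each = p),
      y_m = rep(s$meta$y_m, each = p),
      wavelength_nm = rep(s$wavelengths, n),
      reflectance = signif(as.vector(t(s$reflectance)), 9))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Average replicate spectra per sample
#'
#' Collapses each (sample, device, condition) group to the arithmetic mean
#' of its replicate spectra. The `n_replicates` metadata column records how
#' many replicates entered each mean.
#'
#' @param s a [spectrum_set()].
#' @return A [spectrum_set()] with one spectrum per sample per
#'   device/condition.
#' @export
average_replicates <- function(s) {
  key <- paste(s$meta$sample_id, s$meta$device, s$meta$condition, sep = "\r")
  groups <- split(seq_len(n_spectra(s)), key)
  # preserve first-appearance order
  groups <- groups[unique(key)]
  refl <- matrix(NA_real_, length(groups), length(s$wavelengths))
  meta <- s$meta[vapply(groups, `[`, 0L, 1), , drop = FALSE]
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    if (length(idx) == 0) stop("no surviving replicates for ", names(groups)[i])
    refl[i, ] <- colMeans(s$reflectance[idx, , drop = FALSE])
  }
  meta$replicate_id <- "mean"
  meta$n_replicates <- lengths(groups)
  rownames(meta) <- NULL
  spectrum_set(s$wavelengths, refl, meta)
}

#' Select the k stream spectra nearest to each sampling point
#'
#' For on-the-go data: for every sample location, picks the `k`
#' georeferenced stream spectra with the smallest planar Euclidean distance,
#' optionally within a maximum radius, and tags them with that sample's id.
#' Ties are broken by stream record order.
#'
#' @param stream a [spectrum_set()] with coordinates per spectrum.
#' @param samples a [sample_table()].
#' @param k number of spectra to select per sample.
#' @param max_radius_m optional maximum distance in metres (default `Inf`);
#'   the study design uses 3 m to emulate a within-plot constraint.
#' @return A [spectrum_set()] with `k` spectra per sample (fewer, with a
#'   warning, where the stream is too sparse; the metadata column
#'   `n_candidates` records availability).
#' @export
select_nearest_stream <- function(stream, samples, k = 10, max_radius_m = Inf) {
  if (k < 1) stop("k must be >= 1")
  if (anyNA(stream$meta$x_m) || anyNA(stream$meta$y_m))
    stop("stream spectra must carry planar coordinates")
  rows <- integer(0)
  sample_of <- character(0)
  ncand <- integer(0)
  for (i in seq_len(nrow(samples))) {
    d2 <- (stream$meta$x_m - samples$x_m[i])^2 +
          (stream$meta$y_m - samples$y_m[i])^2
    cand <- which(d2 <= max_radius_m^2)
    if (length(cand) < k)
      warning("sample ", samples$sample_id[i], ": only ", length(cand),
              " stream spectra available (k = ", k, ")")
    take <- cand[order(d2[cand], cand)][seq_len(min(k, length(cand)))]
    rows <- c(rows, take)
    sample_of <- c(sample_of, rep(samples$sample_id[i], length(take)))
    ncand <- c(ncand, rep(length(cand), length(take)))
  }
  meta <- stream$meta[rows, , drop = FALSE]
  meta$sample_id <- sample_of
  meta$replicate_id <- as.character(stats::ave(
    seq_along(sample_of), sample_of, FUN = seq_along))
  meta$n_candidates <- ncand
  rownames(meta) <- NULL
  spectrum_set(stream$wavelengths,
               stream$reflectance[rows, , drop = FALSE], meta)
}
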