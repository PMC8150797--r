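#' Average replicate spectra of one sample
#'
#' Pointwise arithmetic mean of the absorbance of replicate measurements on
#' identical grids. Averaging precedes differentiation in the standard
#' workflow: repeated ATR measurements are averaged, then the mean spectrum
#' is differentiated.
#'
#' @param spectra List of [ir_spectrum] objects with identical grids.
#' @param method `"mean"` (default) or `"median"` pointwise summary.
#' @return An [ir_spectrum] with `replicate = 0`.
#' @export
average_replicates <- function(spectra, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "ir_spectrum")))
  w <- spectra[[1]]$wavenumber
  for (s in spectra[-1]) {
    if (length(s$wavenumber) != length(w) ||
        max(abs(s$wavenumber - w)) > 1e-9 * max(abs(w)))
      stop("incompatible grids: replicates must share the same wavenumber grid")
  }
  y <- vapply(spectra, function(s) s$absorbance, numeric(length(w)))
  y <- if (length(spectra) == 1L) spectra[[1]]$absorbance
       else if (method == "mean") rowMeans(y) else apply(y, 1, stats::median)
  ir_spectrum(w, y, sample_id = spectra[[1]]$sample_id, replicate = 0L,
              origin = spectra[[1]]$origin)
}

#' Resample a spectrum onto a uniform grid
#'
#' Linear interpolation onto an evenly spaced grid (default spacing: the
#' median of the existing spacings). Savitzky-Golay differentiation assumes
#' uniform spacing, so non-uniform spectra must pass through this step first.
#'
#' @param s An [ir_spectrum].
#' @param spacing Target spacing in cm^-1.
#' @return A uniform-grid [ir_spectrum].
#' @export
resample_uniform <- function(s, spacing = grid_spacing(s)) {
  stopifnot(inherits(s, "ir_spectrum"), spacing > 0)
  w <- seq(min(s$wavenumber), max(s$wavenumber), by = spacing)
  y <- stats::approx(s$wavenumber, s$absorbance, xout = w)$y
  ir_spectrum(w, y, sample_id = s$sample_id, replicate = s$replicate,
              origin = s$origin)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Computes d2A/dnu2 by local least-squares polynomial fitting (third-order
#' polynomials over seven points by default, the standard setting for
#' second-derivative FT-IR work). Edge points are handled by one-sided
#' polynomial fits. The filter is exact on polynomials up to the fitting
#' order, so quadratic inputs return their exact constant second derivative
#' and any linear baseline is annihilated.
#'
#' @param s An [ir_spectrum] on a uniform grid.
#' @param window_points Odd window length (default 7).
#' @param poly_order Polynomial order (default 3; must be < `window_points`).
#' @return An [ir_spectrum] whose `absorbance` field holds the second
#'   derivative (absorbance * cm^2) on the same grid.
#' @export
sg_second_derivative <- function(s, window_points = 7L, poly_order = 3L) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (window_points %% 2L == 0L)
    stop("window_points must be odd")
  if (!s$uniform)
    stop("non-uniform wavenumber grid: resample with resample_uniform() ",
         "before differentiation")
  if (window_points > length(s$wavenumber))
    stop("window_points exceeds the spectrum length")
  if (poly_order >= window_points)
    stop("poly_order must be smaller than window_points")
  if (poly_order < 2L)
    stop("poly_order must be at least 2 for a second derivative")
  h <- grid_spacing(s)
  d2 <- signal::sgolayfilt(s$absorbance, p = poly_order, n = window_points,
                           m = 2, ts = h)
  ir_spectrum(s$wavenumber, d2, sample_id = s$sample_id,
              replicate = s$replicate, origin = s$origin)
}

#' The packaged peak catalogue
#'
#' The 19 bands used as peak variables in the second-derivative spectrum of
#' red pepper powder, P1 (3010 cm^-1) down to P19 (1008 cm^-1, the C-O
#' stretching reference band), with their functional-group assignments as
#' metadata.
#'
#' @param halfwidth Search half-width in cm^-1 attached to every definition
#'   (default 8, two steps of the nominal 4 cm^-1 instrument resolution).
#' @return A data frame with columns `label`, `wavenumber`,
#'   `functional_group`, `vibration_mode`, `search_halfwidth`.
#' @export
default_peak_catalogue <- function(halfwidth = 8) {
  path <- system.file("extdata", "peak_catalogue.csv", package = "ftirorigin")
  defs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(defs$label)) stop("duplicate labels in peak catalogue")
  if (any(diff(defs$wavenumber) >= 0))
    stop("catalogue wavenumbers must be strictly decreasing from P1 to P19")
  defs$search_halfwidth <- halfwidth
  defs
}

#' Extract peak amplitudes from a second-derivative spectrum
#'
#' Absorbance bands appear as local minima of the second derivative. For
#' each catalogue entry the deepest local minimum within
#' `nominal +/- search_halfwidth` is located and its magnitude returned as a
#' positive amplitude. The minimum is refined by parabolic interpolation
#' through the neighbouring points (`refine = TRUE`) to remove the
#' grid-offset dependence of the sampled depth.
#'
#' @param deriv Second-derivative [ir_spectrum] (from
#'   [sg_second_derivative]).
#' @param defs Peak definitions: data frame with `label`, `wavenumber` and
#'   optionally `search_halfwidth` columns (default
#'   [default_peak_catalogue()]).
#' @param halfwidth Fallback search half-width (cm^-1) when `defs` lacks a
#'   `search_halfwidth` column.
#' @param refine Parabolic sub-grid refinement of the minimum depth.
#' @return Named numeric vector of absolute amplitudes, one per label.
#' @export
extract_peaks <- function(deriv, defs = default_peak_catalogue(),
                          halfwidth = 8, refine = TRUE) {
  stopifnot(inherits(deriv, "ir_spectrum"))
  if (is.null(defs$search_halfwidth)) defs$search_halfwidth <- halfwidth
  w <- deriv$wavenumber; y <- deriv$absorbance; n <- length(w)
  out <- stats::setNames(numeric(nrow(defs)), defs$label)
  for (r in seq_len(nrow(defs))) {
    lo <- defs$wavenumber[r] - defs$search_halfwidth[r]
    hi <- defs$wavenumber[r] + defs$search_halfwidth[r]
    if (lo < w[1] || hi > w[n])
      stop(sprintf("coverage error: window [%.1f, %.1f] for %s exceeds the spectrum",
                   lo, hi, defs$label[r]))
    idx <- which(w >= lo & w <= hi)
    # local minima w.r.t. immediate neighbours (which may lie outside window)
    cand <- idx[idx > 1L & idx < n]
    cand <- cand[y[cand] <= y[cand - 1L] & y[cand] <= y[cand + 1L] &
                 (y[cand] < y[cand - 1L] | y[cand] < y[cand + 1L])]
    if (!length(cand))
      stop(sprintf("missing peak: no local minimum for %s in [%.1f, %.1f] cm^-1",
                   defs$label[r], lo, hi))
    i <- cand[which.min(y[cand])]
    depth <- y[i]
    if (refine) {
      y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
      den <- y0 - 2 * y1 + y2
      if (den > 0) {                       # strictly convex: parabola vertex
        delta <- 0.5 * (y0 - y2) / den
        if (abs(delta) <= 1) depth <- y1 - 0.25 * (y0 - y2) * delta
      }
    }
    out[defs$label[r]] <- abs(depth)
  }
  out
}

#' Normalize raw peak amplitudes by the 1008 cm^-1 reference band
#'
#' Divides every amplitude P1...P18 by the P19 amplitude and drops P19,
#' yielding dimensionless variables invariant to global intensity rescaling
#' of the spectrum (ATR contact/path-length invariance).
#'
#' @param raw Named numeric vector including `P19 > 0`.
#' @return Named numeric vector over the remaining labels.
#' @export
normalize_peaks <- function(raw) {
  if (!("P19" %in% names(raw)) || !is.finite(raw[["P19"]]) || raw[["P19"]] <= 0)
    stop("normalization error: reference peak P19 is missing or non-positive")
  ref <- raw[["P19"]]
  out <- raw[setdiff(names(raw), "P19")] / ref
  out
}

#' Build a peak table from replicate spectra
#'
#' Runs the full preprocessing chain for each sample: replicate averaging,
#' Savitzky-Golay second derivative, peak extraction, and reference-band
#' normalization.
#'
#' @param spectra_by_sample Named list: for each sample, a list of replicate
#'   [ir_spectrum] objects.
#' @param origins Optional named character vector of origin labels.
#' @param defs Peak definitions (see [extract_peaks]).
#' @param window_points,poly_order Savitzky-Golay settings.
#' @param average `"mean"` or `"median"` replicate averaging.
#' @return A [peak_table] with one row per sample.
#' @export
build_peak_table <- function(spectra_by_sample, origins = NULL,
                             defs = default_peak_catalogue(),
                             window_points = 7L, poly_order = 3L,
                             average = "mean") {
  rows <- lapply(names(spectra_by_sample), function(id) {
    avg <- average_replicates(spectra_by_sample[[id]], method = average)
    if (!avg$uniform) avg <- resample_uniform(avg)
    d2 <- sg_second_derivative(avg, window_points, poly_order)
    vals <- normalize_peaks(extract_peaks(d2, defs))
    c(list(sample_id = id,
           origin = if (!is.null(origins)) origins[[id]] else avg$origin),
      as.list(vals))
  })
  peak_table(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
}
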