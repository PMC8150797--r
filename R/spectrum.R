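#' Construct an IR spectrum
#'
#' An `ir_spectrum` is a sampled absorbance trace on a strictly monotone
#' wavenumber grid, together with sample/replicate metadata. Grids are
#' canonicalized to ascending order on construction; all window and index
#' conventions in the package assume ascending grids.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly monotone
#'   in either direction.
#' @param absorbance Numeric vector of absorbance values, same length.
#' @param sample_id Sample identifier.
#' @param replicate Replicate number (>= 1; 0 denotes a replicate average).
#' @param origin Optional origin label (e.g. "Korean", "Chinese",
#'   "Vietnamese"); `NA` for unknown.
#' @return An object of class `ir_spectrum`: a list with elements
#'   `wavenumber`, `absorbance`, `sample_id`, `replicate`, `origin` and
#'   `uniform` (logical; whether the grid spacing is uniform to relative
#'   tolerance 1e-6).
#' @export
ir_spectrum <- function(wavenumber, absorbance, sample_id = "", replicate = 1L,
                        origin = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance must have the same length")
  if (length(wavenumber) < 7L)
    stop("input too short: a spectrum needs at least 7 points")
  if (anyNA(wavenumber) || anyNA(absorbance))
    stop("spectrum contains missing values")
  d <- diff(wavenumber)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("wavenumbers must be strictly monotone")
  if (d[1] < 0) { # canonicalize to ascending
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
    d <- -rev(d)
  }
  structure(
    list(wavenumber = wavenumber, absorbance = absorbance,
         sample_id = as.character(sample_id),
         replicate = as.integer(replicate),
         origin = as.character(origin),
         uniform = is_uniform_grid(wavenumber)),
    class = "ir_spectrum")
}

# uniform spacing within relative tolerance 1e-6
is_uniform_grid <- function(w, rtol = 1e-6) {
  d <- diff(w)
  h <- stats::median(d)
  all(abs(d - h) <= rtol * abs(h))
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("IR spectrum '%s' (replicate %d%s)\n", x$sample_id, x$replicate,
              if (is.na(x$origin)) "" else paste0(", ", x$origin)))
  cat(sprintf("  %d points, %.1f-%.1f cm^-1, %s grid\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              if (x$uniform) "uniform" else "non-uniform"))
  invisible(x)
}

#' @export
format.ir_spectrum <- function(x, ...) {
  sprintf("<ir_spectrum %s: %d pts>", x$sample_id, length(x$wavenumber))
}

grid_spacing <- function(s) stats::median(diff(s$wavenumber))
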