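#' Read a two-column spectrum CSV
#'
#' Reads a wavenumber/absorbance file (comma- or tab-delimited, header
#' optional) and returns a canonicalized [ir_spectrum]. Descending grids are
#' reversed to ascending; non-uniform grids are accepted but flagged via the
#' `uniform` field (resampling is the responsibility of
#' [sg_second_derivative] callers, see [resample_uniform]).
#'
#' @param path File path.
#' @param sample_id,replicate,origin Metadata attached to the spectrum.
#' @return An [ir_spectrum].
#' @export
read_spectrum_csv <- function(path, sample_id = basename(path), replicate = 1L,
                              origin = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  skip <- suppressWarnings(any(is.na(as.numeric(first[1:2]))))
  start <- if (skip) 2L else 1L
  n <- length(lines) - start + 1L
  w <- numeric(n); a <- numeric(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[start + i - 1L]], sep, fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2L || anyNA(v))
      stop(sprintf("parse error at line %d of %s: non-numeric row '%s'",
                   start + i - 1L, path, lines[[start + i - 1L]]))
    w[i] <- v[1]; a[i] <- v[2]
  }
  ir_spectrum(w, a, sample_id = sample_id, replicate = replicate,
              origin = origin)
}

#' Write a spectrum to a two-column CSV
#'
#' Values are rendered with `%.17g` so that doubles round-trip exactly
#' through [read_spectrum_csv].
#'
#' @param s An [ir_spectrum].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "ir_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavenumber,absorbance", con)
  writeLines(sprintf("%.17g,%.17g", s$wavenumber, s$absorbance), con)
  invisible(path)
}

#' Read a JCAMP-DX spectrum (AFFN encodings only)
#'
#' Minimal reader for single-block JCAMP-DX files with `##XYDATA=(X++(Y..Y))`
#' or `##XYPOINTS=(XY..XY)` sections in plain AFFN (free-form numeric)
#' encoding. `XFACTOR`/`YFACTOR` scaling is applied; for XYDATA the grid is
#' reconstructed from `FIRSTX`/`LASTX`/`NPOINTS`. Compressed encodings
#' (SQZ/DIF/PAC pseudo-digits) are rejected.
#'
#' @inheritParams read_spectrum_csv
#' @return An [ir_spectrum].
#' @export
read_jcampdx <- function(path, sample_id = basename(path), replicate = 1L,
                         origin = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  ldr <- grep("^##", lines)
  get <- function(label) {
    i <- grep(paste0("^##", label, "\\s*="), lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    trimws(sub("^##[^=]*=", "", lines[[i[1]]]))
  }
  num <- function(label, default = NULL) {
    v <- get(label)
    if (is.null(v)) default else as.numeric(v)
  }
  xy_i <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  xp_i <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  if (!length(xy_i) && !length(xp_i))
    stop("format error: no ##XYDATA or ##XYPOINTS block in ", path)
  start <- if (length(xy_i)) xy_i[1] else xp_i[1]
  stop_at <- ldr[ldr > start]
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  body <- lines[seq(start + 1L, end)]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-DF-Za-df-z@%]", body)))
    stop("unsupported encoding: SQZ/DIF/PAC compressed JCAMP data ",
         "(only AFFN is supported)")
  xf <- num("XFACTOR", 1); yf <- num("YFACTOR", 1)
  if (length(xy_i)) {
    firstx <- num("FIRSTX"); lastx <- num("LASTX"); npts <- num("NPOINTS")
    if (is.null(firstx) || is.null(npts))
      stop("format error: XYDATA requires ##FIRSTX and ##NPOINTS")
    deltax <- num("DELTAX",
                  if (!is.null(lastx)) (lastx - firstx) / (npts - 1) else NULL)
    if (is.null(deltax)) stop("format error: cannot determine DELTAX")
    y <- unlist(lapply(body, function(l) {
      f <- as.numeric(strsplit(trimws(l), "[,;[:space:]]+")[[1]])
      f[-1]  # first field is the line's X value
    }))
    if (length(y) != npts)
      stop(sprintf("format error: NPOINTS=%d but %d Y values found",
                   npts, length(y)))
    w <- firstx + deltax * (seq_len(npts) - 1L)
    a <- y * yf
  } else {
    f <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    if (length(f) %% 2L != 0L) stop("format error: odd number of XY fields")
    w <- f[seq(1, length(f), by = 2)] * xf
    a <- f[seq(2, length(f), by = 2)] * yf
  }
  ir_spectrum(w, a, sample_id = sample_id, replicate = replicate,
              origin = origin)
}

#' Read a sample manifest
#'
#' A manifest CSV has columns `sample_id`, `origin` and `paths`, the latter a
#' `;`-separated list of spectrum files (relative paths are resolved against
#' the manifest's directory). Origins may be empty/`unknown` only when
#' `require_origin = FALSE` (blind manifests).
#'
#' @param path Manifest CSV path.
#' @param require_origin If `TRUE`, fail when any origin is missing.
#' @return A data frame with columns `sample_id`, `origin` and list-column
#'   `paths`.
#' @export
read_manifest <- function(path, require_origin = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "origin", "paths")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_ids in manifest")
  m$origin[m$origin %in% c("", "unknown", "NA")] <- NA_character_
  if (require_origin && anyNA(m$origin))
    stop("training manifest has samples with unknown origin")
  base <- dirname(normalizePath(path))
  m$paths <- lapply(strsplit(m$paths, ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  })
  missing <- unlist(m$paths)[!file.exists(unlist(m$paths))]
  if (length(missing))
    stop("manifest refers to missing files: ",
         paste(utils::head(missing, 3), collapse = ", "))
  m
}
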