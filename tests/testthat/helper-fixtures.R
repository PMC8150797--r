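# Shared fixture builders: everything is generated in code at test time.

# analytic Gaussian band and its exact second derivative
gauss_band <- function(w, center, sigma, amplitude = 1) {
  amplitude * exp(-(w - center)^2 / (2 * sigma^2))
}
gauss_band_d2 <- function(w, center, sigma, amplitude = 1) {
  gauss_band(w, center, sigma, amplitude) *
    ((w - center)^2 / sigma^4 - 1 / sigma^2)
}

# an analytic second-derivative spectrum over the full catalogue window
analytic_d2_spectrum <- function(centers, sigmas, amplitudes,
                                 wn = seq(400, 4000, by = 1)) {
  y <- numeric(length(wn))
  for (i in seq_along(centers))
    y <- y + gauss_band_d2(wn, centers[i], sigmas[i], amplitudes[i])
  ir_spectrum(wn, y, sample_id = "analytic")
}

# small labeled table with 2 well-separated groups in 2 variables
two_group_table <- function(n = 12, delta = c(3, 1), seed = 7) {
  set.seed(seed)
  g <- rep(c("A", "B"), each = n)
  peak_table(data.frame(
    sample_id = sprintf("s%02d", seq_len(2 * n)), origin = g,
    P1 = rnorm(2 * n, ifelse(g == "B", delta[1], 0) + 5, 1),
    P2 = rnorm(2 * n, ifelse(g == "B", delta[2], 0) + 5, 1)))
}

# three-group table with configurable separation (in pooled-sd units)
three_group_table <- function(n = c(10, 8, 6), sep = 4, p = 3, seed = 11,
                              sd = 1) {
  set.seed(seed)
  origins <- c("Korean", "Chinese", "Vietnamese")
  centers <- rbind(rep(0, p), rep(sep, p) * rep_len(c(1, 0), p),
                   rep(sep, p) * rep_len(c(0, 1), p)) * sd
  rows <- lapply(1:3, function(g) {
    x <- sapply(seq_len(p), function(j) rnorm(n[g], centers[g, j] + 5, sd))
    if (n[g] == 1L) x <- matrix(x, 1)
    df <- as.data.frame(x)
    names(df) <- paste0("P", seq_len(p))
    cbind(sample_id = sprintf("%s%02d", substr(origins[g], 1, 1),
                              seq_len(n[g])),
          origin = origins[g], df, stringsAsFactors = FALSE)
  })
  peak_table(do.call(rbind, rows))
}

# write a minimal AFFN JCAMP-DX file for a uniform-grid spectrum
write_jcamp <- function(w, y, path, yfactor = 1, xydata = TRUE) {
  stopifnot(length(w) == length(y))
  h <- w[2] - w[1]
  lines <- c("##TITLE=synthetic test spectrum", "##JCAMP-DX=4.24",
             "##DATA TYPE=INFRARED SPECTRUM", "##XUNITS=1/CM",
             "##YUNITS=ABSORBANCE", "##XFACTOR=1",
             sprintf("##YFACTOR=%.17g", yfactor),
             sprintf("##FIRSTX=%.17g", w[1]),
             sprintf("##LASTX=%.17g", w[length(w)]),
             sprintf("##DELTAX=%.17g", h),
             sprintf("##NPOINTS=%d", length(w)))
  if (xydata) {
    lines <- c(lines, "##XYDATA=(X++(Y..Y))")
    idx <- split(seq_along(w), ceiling(seq_along(w) / 6))
    for (ii in idx)
      lines <- c(lines, paste(c(sprintf("%.17g", w[ii[1]]),
                                sprintf("%.17g", y[ii] / yfactor)),
                              collapse = " "))
  } else {
    lines <- c(lines, "##XYPOINTS=(XY..XY)",
               sprintf("%.17g, %.17g", w, y / yfactor))
  }
  writeLines(c(lines, "##END="), path)
  invisible(path)
}

# independent SG second-derivative convolution weights (central window),
# from the local least-squares polynomial fit normal equations
sg_d2_weights <- function(n = 7, p = 3, h = 1) {
  half <- (n - 1) / 2
  X <- outer(-half:half, 0:p, `^`)
  coef_rows <- solve(crossprod(X), t(X))
  2 * coef_rows[3, ] / h^2
}

# default profiles with the informative within-group spread tightened:
# clearly separated clusters (min pairwise Mahalanobis ~8 sigma at mult = 2)
# without pushing any mean toward the zero-truncation boundary
separated_profiles <- function(mult = 2) {
  pr <- default_origin_profiles()
  pr$sds[, pr$informative] <- pr$sds[, pr$informative] / mult
  pr
}
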