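#' Default origin profiles for the synthetic peak-table generator
#'
#' Three-origin multivariate structure over the 18 normalized peak
#' variables. Eight variables (P5, P7, P8, P10, P12, P14, P16, P17) carry
#' origin-shifted means with a shared within-group standard deviation; the
#' remaining ten are nulls: equal means with origin-dependent dispersion, so
#' they fail the variance-homogeneity screen by design. The four indicator
#' variables are calibrated to the per-origin medians and pooled
#' within-origin spread of the packaged 19-sample blind reference table;
#' the qualitative pattern is Korean low in P8/P12, Vietnamese low in P17,
#' Chinese high.
#'
#' @return List with `means` (origin x variable matrix), `sds` (same shape),
#'   and `informative` (labels of the mean-shifted variables).
#' @export
default_origin_profiles <- function() {
  origins <- c("Korean", "Chinese", "Vietnamese")
  vars <- paste0("P", 1:18)
  means <- matrix(NA_real_, 3, 18, dimnames = list(origins, vars))
  sds <- matrix(NA_real_, 3, 18, dimnames = list(origins, vars))

  # informative variables: shifted means, shared (homogeneous) sd
  inf <- rbind( # Korean, Chinese, Vietnamese, sd
    P5  = c(2.10, 2.60, 2.90, 0.35),
    P7  = c(0.55, 0.62, 0.68, 0.12),
    P8  = c(1.903, 4.544, 5.320, 0.9226),  # blind-table medians / pooled sd
    P10 = c(0.70, 0.85, 0.98, 0.14),
    P12 = c(0.549, 1.525, 1.919, 0.3501),
    P14 = c(0.772, 1.437, 1.648, 0.2396),
    P16 = c(1.10, 1.25, 1.40, 0.18),
    P17 = c(0.782, 0.921, 0.617, 0.0896))
  for (v in rownames(inf)) {
    means[, v] <- inf[v, 1:3]
    sds[, v] <- inf[v, 4]
  }
  # null variables: common mean, heterogeneous per-origin dispersion
  null_means <- c(P1 = 0.40, P2 = 1.20, P3 = 2.50, P4 = 1.40, P6 = 0.60,
                  P9 = 1.10, P11 = 0.90, P13 = 0.70, P15 = 0.90, P18 = 1.30)
  sd_mult <- c(Korean = 0.05, Chinese = 0.15, Vietnamese = 0.30)
  for (v in names(null_means)) {
    means[, v] <- null_means[[v]]
    sds[, v] <- sd_mult * null_means[[v]]
  }
  list(means = means, sds = sds, informative = rownames(inf))
}

#' Simulation configuration
#'
#' Bundles everything the synthetic generators need: group sizes matching
#' the reference study design (50 Korean / 23 Chinese / 13 Vietnamese),
#' origin profiles, the Gaussian band model on the packaged catalogue
#' positions, baseline polynomial, noise level, replicate count and grid.
#'
#' @param group_sizes Named integer vector of samples per origin.
#' @param profiles As returned by [default_origin_profiles] (optionally with
#'   a `cov` element: per-origin list of full covariance matrices overriding
#'   the diagonal `sds`).
#' @param band_sigma Gaussian band width (sd, cm^-1) shared by all bands.
#' @param ref_amplitude Absorbance amplitude of the P19 reference band.
#' @param baseline Polynomial baseline coefficients `c(a0, a1, ...)` in
#'   powers of wavenumber (default a small linear drift, which the second
#'   derivative annihilates).
#' @param noise_sd Absorbance white-noise sd per point.
#' @param replicates Replicate spectra per sample (default 5).
#' @param spacing Grid spacing in cm^-1 (default 2, half the nominal 4 cm^-1
#'   instrument resolution).
#' @param wn_range Wavenumber range, cm^-1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c(Korean = 50, Chinese = 23,
                                       Vietnamese = 13),
                       profiles = default_origin_profiles(),
                       band_sigma = 2.5, ref_amplitude = 0.25,
                       baseline = c(0.05, 1e-5), noise_sd = 0.001,
                       replicates = 5L, spacing = 2,
                       wn_range = c(400, 4000)) {
  stopifnot(all(group_sizes >= 1), band_sigma > 0, ref_amplitude > 0,
            noise_sd >= 0, replicates >= 1, spacing > 0)
  structure(list(group_sizes = group_sizes, profiles = profiles,
                 band_sigma = band_sigma, ref_amplitude = ref_amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 replicates = as.integer(replicates), spacing = spacing,
                 wn_range = wn_range),
            class = "sim_config")
}

#' Simulate a labeled peak table
#'
#' Draws each sample's variable vector from its origin's multivariate
#' normal (diagonal by default; full covariance if the profiles carry one),
#' clipped at zero — normalized amplitudes are non-negative by construction.
#' A warning is raised when more than 1% of draws clip.
#'
#' @param config A [sim_config].
#' @param seed Optional integer seed; fixed seed implies identical output.
#' @return A labeled [peak_table].
#' @export
simulate_peak_table <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- config$profiles
  vars <- colnames(pr$means)
  rows <- list(); clipped <- 0L; total <- 0L
  for (o in rownames(pr$means)) {
    n <- config$group_sizes[[o]]
    if (!is.null(pr$cov)) {
      S <- pr$cov[[o]]
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev)))
        stop("config error: covariance for ", o,
             " is not positive semi-definite")
      L <- chol(S + diag(1e-12, nrow(S)))
      z <- matrix(stats::rnorm(n * length(vars)), n)
      x <- sweep(z %*% L, 2, pr$means[o, ], "+")
    } else {
      x <- sapply(vars, function(v)
        stats::rnorm(n, pr$means[o, v], pr$sds[o, v]))
      if (n == 1L) x <- matrix(x, nrow = 1L, dimnames = list(NULL, vars))
    }
    clipped <- clipped + sum(x < 0); total <- total + length(x)
    x[x < 0] <- 0
    df <- as.data.frame(x)
    colnames(df) <- vars
    df <- cbind(sample_id = sprintf("%s%03d", substr(o, 1, 1), seq_len(n)),
                origin = o, df, stringsAsFactors = FALSE)
    rows[[o]] <- df
  }
  if (clipped > 0.01 * total)
    warning(sprintf("%.1f%% of simulated draws clipped at zero",
                    100 * clipped / total))
  peak_table(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Simulate replicate raw spectra for one sample
#'
#' Builds an absorbance spectrum as a sum of Gaussian bands at the packaged
#' catalogue wavenumbers — band j's amplitude is the sample's normalized
#' variable value times the P19 reference amplitude, so the preprocessing
#' chain (average, second derivative, extract, normalize) recovers the
#' input vector for well-separated bands — plus a polynomial baseline and
#' white noise. Replicates differ only in the noise.
#'
#' @param values Named numeric vector of normalized variables `P1`...`P18`.
#' @param config A [sim_config].
#' @param sample_id,origin Metadata for the emitted spectra.
#' @param seed Optional integer seed.
#' @return List of `config$replicates` [ir_spectrum] objects.
#' @export
simulate_spectrum <- function(values, config = sim_config(),
                              sample_id = "sim", origin = NA_character_,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  defs <- default_peak_catalogue()
  w <- seq(config$wn_range[1], config$wn_range[2], by = config$spacing)
  amp <- stats::setNames(numeric(nrow(defs)), defs$label)
  amp["P19"] <- config$ref_amplitude
  for (v in setdiff(defs$label, "P19")) {
    if (!(v %in% names(values)))
      stop("values must cover all catalogue bands; missing ", v)
    amp[v] <- values[[v]] * config$ref_amplitude
  }
  clean <- numeric(length(w))
  for (r in seq_len(nrow(defs)))
    clean <- clean + amp[[defs$label[r]]] *
      exp(-(w - defs$wavenumber[r])^2 / (2 * config$band_sigma^2))
  for (d in seq_along(config$baseline))
    clean <- clean + config$baseline[d] * w^(d - 1)
  lapply(seq_len(config$replicates), function(rep) {
    ir_spectrum(w, clean + stats::rnorm(length(w), 0, config$noise_sd),
                sample_id = sample_id, replicate = rep, origin = origin)
  })
}

#' Simulate a full spectral dataset on disk
#'
#' Draws a peak table from the origin profiles, renders replicate spectra
#' for every sample, and writes spectrum CSVs, a manifest and the
#' ground-truth peak table into a directory — the inputs the pipeline (and
#' its oracles) consume.
#'
#' @param config A [sim_config].
#' @param dir Output directory (created if needed).
#' @param seed Optional integer seed covering both stages.
#' @return List with `manifest` (path), `truth` (path to the ground-truth
#'   peak table CSV) and `table` (the in-memory truth [peak_table]).
#' @export
simulate_spectra_set <- function(config = sim_config(), dir = tempfile("sim"),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_peak_table(config)
  pv <- peak_vars(truth)
  man <- data.frame(sample_id = truth$sample_id, origin = truth$origin,
                    paths = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(truth))) {
    reps <- simulate_spectrum(unlist(truth[i, pv]), config,
                              sample_id = truth$sample_id[i],
                              origin = truth$origin[i])
    paths <- sprintf("%s_r%d.csv", truth$sample_id[i], seq_along(reps))
    for (j in seq_along(reps))
      write_spectrum_csv(reps[[j]], file.path(dir, paths[j]))
    man$paths[i] <- paste(paths, collapse = ";")
  }
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  truth_path <- file.path(dir, "truth_peak_table.csv")
  write_peak_table(truth, truth_path)
  list(manifest = man_path, truth = truth_path, table = truth)
}
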