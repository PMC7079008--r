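#' Design for a synthetic reduction time course
#'
#' Specifies the ground truth and sampling of a simulated reduction
#' experiment. Defaults mirror the reference NMR monitoring experiment:
#' 0.113 mmol/L protein, an 18-fold molar excess of reducing agent,
#' 40 log-spaced samples out to 3300 min (sampling denser in the early
#' reduction phase) and additive Gaussian noise with standard deviation
#' 2 percent of the initial protein concentration.
#'
#' @param truth a [rate_constants()]
#' @param ss0 initial oxidized protein, mmol/L
#' @param red0 initial reducing agent, mmol/L
#' @param o2_0 initial dissolved oxygen, mmol/L
#' @param t_end_min last sample time, minutes
#' @param n_points number of samples (first at t = 0)
#' @param spacing `"log"` (denser early sampling) or `"linear"`
#' @param noise_sigma noise sd as a fraction of `ss0` (>= 0)
#' @param seed integer RNG seed; mandatory when `noise_sigma > 0`
#' @param forward_model raw-signal table(s) to emit alongside the series:
#'   `"nmr_integrals"`, `"ecd_trace"` or `"both"`
#' @param temperature_c metadata, degrees Celsius
#' @return a `synthetic_design` list
#' @export
synthetic_design <- function(truth = rate_constants(k1 = 8.03e-4),
                             ss0 = 0.113, red0 = 18 * 0.113, o2_0 = 0,
                             t_end_min = 3300, n_points = 40,
                             spacing = c("log", "linear"),
                             noise_sigma = 0.02, seed = NULL,
                             forward_model = c("both", "nmr_integrals", "ecd_trace"),
                             temperature_c = 15) {
  spacing <- match.arg(spacing)
  forward_model <- match.arg(forward_model)
  truth <- as_rate_constants(truth)
  stopifnot(ss0 > 0, red0 >= 0, o2_0 >= 0, t_end_min > 0, n_points >= 5,
            noise_sigma >= 0)
  if (noise_sigma > 0 && is.null(seed)) {
    stop("'seed' is mandatory when noise_sigma > 0", call. = FALSE)
  }
  structure(list(truth = truth, ss0 = ss0, red0 = red0, o2_0 = o2_0,
                 t_end_min = t_end_min, n_points = n_points,
                 spacing = spacing, noise_sigma = noise_sigma, seed = seed,
                 forward_model = forward_model, temperature_c = temperature_c),
            class = "synthetic_design")
}

.design_times <- function(design) {
  n <- design$n_points
  if (design$spacing == "log") {
    c(0, exp(seq(log(design$t_end_min / 500), log(design$t_end_min),
                 length.out = n - 1)))
  } else {
    seq(0, design$t_end_min, length.out = n)
  }
}

#' Generate a synthetic reduction time course with known truth
#'
#' Integrates the mechanism at the design's true parameters, adds i.i.d.
#' Gaussian noise of sd `noise_sigma * ss0` to the sampled `[SS]` (and
#' `[2SH]`) concentrations, and emits the raw-signal tables of the chosen
#' forward model: NMR integrals proportional to the concentrations (times a
#' reference-standard integral) and/or an ellipticity trace through the
#' affine CD map. The raw tables are generated from the noisy
#' concentrations, so converting them back through [nmr_to_concentrations()]
#' or [ecd_to_concentration()] reproduces the observed series exactly.
#' A fixed seed gives bit-identical output. Noise is left unclipped, so
#' near-zero late-time readings can be slightly negative, as in real
#' baseline-subtracted data.
#'
#' @param design a [synthetic_design()]
#' @return list with elements `series` (an [observed_series()] carrying the
#'   truth in its `truth` attribute), `truth`, and, per the forward model,
#'   `integrals` (`time_min,int_ox,int_red,int_dss`) and/or
#'   `trace` (an [ellipticity_trace()])
#' @export
synth_time_course <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  times <- .design_times(design)
  tc <- simulate_redox(design$truth,
                       system_state(ss = design$ss0, red = design$red0,
                                    o2 = design$o2_0),
                       times)
  ss <- tc$ss
  sh <- tc$sh
  if (design$noise_sigma > 0) {
    set.seed(design$seed)
    sd <- design$noise_sigma * design$ss0
    ss <- ss + stats::rnorm(length(ss), 0, sd)
    sh <- sh + stats::rnorm(length(sh), 0, sd)
  }
  series <- observed_series(times, ss, sh_obs = sh, source = "synthetic",
                            temperature = design$temperature_c,
                            c_red0 = design$red0, ss0 = design$ss0)
  attr(series, "truth") <- design$truth
  out <- list(series = series, truth = design$truth, design = design)

  if (design$forward_model %in% c("nmr_integrals", "both")) {
    int_dss <- 1
    scale <- 100 / design$ss0   # integrals on a 0-100 scale
    out$integrals <- data.frame(time_min = times,
                                int_ox = ss * scale * int_dss,
                                int_red = sh * scale * int_dss,
                                int_dss = int_dss)
  }
  if (design$forward_model %in% c("ecd_trace", "both")) {
    theta_0 <- -10   # typical oxidized band, deg cm^2 dmol^-1
    theta_inf <- 5   # reduced plateau
    theta <- theta_inf + (theta_0 - theta_inf) * ss / design$ss0
    out$trace <- ellipticity_trace(times, theta, wavelength = 287,
                                   theta_0 = theta_0, theta_inf = theta_inf)
  }
  out
}

#' Design for a synthetic thermal CD melt ensemble
#'
#' Two fixed basis curves (each a sum of Gaussian bands emulating the
#' folded "C-type" and unfolded "U-type" far-UV CD shapes) are mixed with a
#' logistic folded fraction per variant and temperature. Defaults emulate a
#' 12-variant by 17-temperature (5-85 C) ensemble of 204 spectra.
#'
#' @param wavelengths nm grid
#' @param folded_basis,unfolded_basis data frames of Gaussian band
#'   parameters (`center` nm, `width` nm, `amplitude` ellipticity units)
#' @param variants data frame with `variant`, `tm_c` (melting midpoint, C)
#'   and `steepness` (logistic slope, 1/C)
#' @param temperatures_c temperatures, degrees Celsius
#' @param noise_sigma noise sd as a fraction of the maximum absolute basis
#'   ellipticity
#' @param seed integer seed; mandatory when `noise_sigma > 0`
#' @return a `melt_design` list
#' @export
melt_design <- function(wavelengths = seq(190, 250, by = 1),
                        folded_basis = data.frame(
                          center = c(192, 208, 222),
                          width = c(6, 7, 9),
                          amplitude = c(55, -32, -30)),
                        unfolded_basis = data.frame(
                          center = c(198, 222),
                          width = c(8, 12),
                          amplitude = c(-40, 2)),
                        variants = data.frame(
                          variant = sprintf("V%02d", 1:12),
                          tm_c = seq(25, 80, length.out = 12),
                          steepness = 0.12),
                        temperatures_c = seq(5, 85, by = 5),
                        noise_sigma = 0, seed = NULL) {
  stopifnot(all(c("center", "width", "amplitude") %in% names(folded_basis)),
            all(c("center", "width", "amplitude") %in% names(unfolded_basis)),
            all(c("variant", "tm_c", "steepness") %in% names(variants)),
            noise_sigma >= 0)
  if (noise_sigma > 0 && is.null(seed)) {
    stop("'seed' is mandatory when noise_sigma > 0", call. = FALSE)
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 folded_basis = folded_basis, unfolded_basis = unfolded_basis,
                 variants = variants, temperatures_c = as.numeric(temperatures_c),
                 noise_sigma = noise_sigma, seed = seed),
            class = "melt_design")
}

.gaussian_curve <- function(wavelengths, bands) {
  rowSums(vapply(seq_len(nrow(bands)), function(i) {
    bands$amplitude[i] * exp(-0.5 * ((wavelengths - bands$center[i]) / bands$width[i])^2)
  }, numeric(length(wavelengths))))
}

#' Generate a synthetic thermal melt ensemble with known fractions
#'
#' Each spectrum is `f(T) * folded + (1 - f(T)) * unfolded + noise`, with
#' `f` a decreasing logistic in temperature crossing 0.5 at the variant's
#' melting midpoint. The ground-truth fractions are attached as the
#' `truth_fractions` attribute of the returned [spectrum_set()].
#'
#' @param design a [melt_design()]
#' @return a `spectrum_set` with attribute `truth_fractions`
#' @export
synth_melt_ensemble <- function(design) {
  stopifnot(inherits(design, "melt_design"))
  wl <- design$wavelengths
  folded <- .gaussian_curve(wl, design$folded_basis)
  unfolded <- .gaussian_curve(wl, design$unfolded_basis)
  nv <- nrow(design$variants)
  nt <- length(design$temperatures_c)
  mat <- matrix(0, length(wl), nv * nt)
  labels <- data.frame(variant = rep(design$variants$variant, each = nt),
                       temperature_c = rep(design$temperatures_c, nv))
  fr <- numeric(nv * nt)
  col <- 0
  for (i in seq_len(nv)) {
    f <- stats::plogis(-(design$temperatures_c - design$variants$tm_c[i]) *
                         design$variants$steepness[i])
    for (j in seq_len(nt)) {
      col <- col + 1
      mat[, col] <- f[j] * folded + (1 - f[j]) * unfolded
      fr[col] <- f[j]
    }
  }
  if (design$noise_sigma > 0) {
    set.seed(design$seed)
    sd <- design$noise_sigma * max(abs(c(folded, unfolded)))
    mat <- mat + matrix(stats::rnorm(length(mat), 0, sd), nrow(mat))
  }
  out <- spectrum_set(wl, mat, labels)
  attr(out, "truth_fractions") <- fr
  attr(out, "bases") <- cbind(folded = folded, unfolded = unfolded)
  out
}
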