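#' Ellipticity trace at a fixed wavelength
#'
#' A near-UV CD band-intensity time course used to monitor disulfide
#' reduction. `theta_0` and `theta_inf` default to the first reading and to
#' the mean over a final plateau window; CD alone cannot give absolute
#' concentrations, so the initial concentration `ss0` must always be
#' supplied externally when converting.
#'
#' @param times minutes
#' @param theta molar ellipticity, deg cm^2 dmol^-1
#' @param wavelength nm (metadata)
#' @param theta_0 initial ellipticity; default `theta[1]`
#' @param theta_inf plateau ellipticity; default mean of the last
#'   `plateau_frac` of the points
#' @param plateau_frac final-window fraction used for the plateau default
#' @return an `ellipticity_trace` list
#' @export
ellipticity_trace <- function(times, theta, wavelength = NA_real_,
                              theta_0 = NULL, theta_inf = NULL,
                              plateau_frac = 0.1) {
  stopifnot(length(times) == length(theta), length(theta) >= 2)
  if (is.null(theta_0)) theta_0 <- theta[1]
  if (is.null(theta_inf)) {
    k <- max(1, ceiling(plateau_frac * length(theta)))
    theta_inf <- mean(utils::tail(theta, k))
  }
  structure(list(times = as.numeric(times), theta = as.numeric(theta),
                 wavelength = wavelength, theta_0 = theta_0,
                 theta_inf = theta_inf),
            class = "ellipticity_trace")
}

#' Convert an ellipticity trace to oxidized-protein concentration
#'
#' Applies the affine signal-to-concentration map
#' \deqn{c(t) = \frac{A_\infty - A(t)}{A_\infty - A_0}\,[SS]_0}
#' where `A` is the monitored band intensity. The map is invariant to adding
#' a constant to, or rescaling, the whole trace. Values falling outside
#' `[0, ss0]` (noise overshoot) are clipped; the number of clipped points is
#' returned in the `n_clipped` attribute.
#'
#' @param trace an [ellipticity_trace()]
#' @param ss0 initial oxidized-protein concentration, mmol/L, > 0
#' @return concentration series, mmol/L, with attribute `n_clipped`
#' @examples
#' tr <- ellipticity_trace(0:10, seq(-10, 5, length.out = 11))
#' ecd_to_concentration(tr, ss0 = 0.113)
#' @export
ecd_to_concentration <- function(trace, ss0) {
  stopifnot(inherits(trace, "ellipticity_trace"), ss0 > 0)
  span <- trace$theta_inf - trace$theta_0
  if (span == 0) {
    stop("degenerate trace: theta_0 equals theta_inf", call. = FALSE)
  }
  conc <- (trace$theta_inf - trace$theta) / span * ss0
  n_clip <- sum(conc < 0 | conc > ss0)
  conc <- pmin(pmax(conc, 0), ss0)
  if (n_clip > 0) {
    warning(sprintf("%d point(s) outside [0, ss0] were clipped", n_clip),
            call. = FALSE)
  }
  structure(conc, n_clipped = n_clip)
}

#' Convert oxidized/reduced NMR integral pairs to concentrations
#'
#' The Trp H-epsilon-1 indole resonance resolves the oxidized and reduced
#' protein; both integrals are normalized to the DSS reference integral
#' (the normalization cancels in the ratio but is kept as a drift
#' diagnostic), and the concentrations follow from the integral ratio and
#' the total protein concentration:
#' `ss = total * int_ox / (int_ox + int_red)`, `sh = total - ss`.
#' Total protein is conserved exactly by construction.
#'
#' @param int_ox,int_red integrals of the oxidized / reduced resonance
#'   (vectors allowed)
#' @param int_ref reference-standard (DSS) integral, > 0
#' @param total_protein total soluble protein, mmol/L
#' @return data frame with columns `ss` and `sh`, mmol/L
#' @examples
#' nmr_to_concentrations(8, 92, 1, 0.115)   # 92:8 reduced:oxidized
#' @export
nmr_to_concentrations <- function(int_ox, int_red, int_ref = 1, total_protein) {
  stopifnot(length(int_ox) == length(int_red), all(int_ref > 0),
            all(int_ox >= 0), all(int_red >= 0))
  ox_n <- int_ox / int_ref
  red_n <- int_red / int_ref
  tot <- ox_n + red_n
  if (any(tot == 0)) {
    stop("both integrals are zero for at least one time point", call. = FALSE)
  }
  ss <- total_protein * ox_n / tot
  data.frame(ss = ss, sh = total_protein - ss)
}

#' CPMG transverse relaxation rate from an intensity ratio
#'
#' \deqn{R_{2,i} = -\ln(I_i / I_{ref}) / t_{CPMG}}
#' A crosspeak brighter than the reference gives a negative rate; this is
#' retained (with a warning) rather than truncated so noise statistics stay
#' unbiased.
#'
#' @param intensity_i crosspeak intensity in spectrum i, > 0
#' @param intensity_ref reference intensity, > 0
#' @param t_cpmg relaxation period, seconds, > 0
#' @return R2 in s^-1
#' @examples
#' cpmg_r2(0.5, 1, 0.04)    # ln 2 / 0.04 ~ 17.3 s^-1
#' @export
cpmg_r2 <- function(intensity_i, intensity_ref, t_cpmg) {
  stopifnot(all(intensity_i > 0), all(intensity_ref > 0), all(t_cpmg > 0))
  r2 <- -log(intensity_i / intensity_ref) / t_cpmg
  if (any(r2 < 0)) {
    warning("negative R2 (intensity above reference) retained as noise",
            call. = FALSE)
  }
  r2
}
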