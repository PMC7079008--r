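#' Rate constants of the disulfide redox mechanism
#'
#' Bundles the four rate constants of the mass-action mechanism used
#' throughout the package:
#' \deqn{SS + Red \rightarrow^{k_1} 2SH + Ox}
#' \deqn{2SH + O_2 \rightarrow^{k_2} SS}
#' \deqn{2SH \rightarrow^{k_3} SS_{precipitated}}
#' \deqn{\emptyset \rightarrow^{k_4} O_2}
#' where `SS` is the disulfide-bonded (oxidized) protein, `2SH` its reduced
#' dithiol form, `Red`/`Ox` the reducing agent (TCEP or DTT) and its spent
#' form, and the fourth reaction is oxygen ingress from the gas phase.
#'
#' Units are fixed package-wide: concentrations in mmol/L, time in minutes,
#' so `k1` and `k2` are in L mmol^-1 min^-1 (numerically equal to
#' mM^-1 min^-1), `k3` in min^-1 and `k4` in mmol L^-1 min^-1.
#'
#' @param k1 second-order reduction rate constant, L mmol^-1 min^-1
#' @param k2 second-order reoxidation rate constant, L mmol^-1 min^-1
#' @param k3 first-order precipitation rate constant, min^-1
#' @param k4 zero-order oxygen ingress rate, mmol L^-1 min^-1
#' @return an object of class `rate_constants` (a named numeric vector)
#' @examples
#' rate_constants(k1 = 8.03e-4)
#' @export
rate_constants <- function(k1 = 0, k2 = 0, k3 = 0, k4 = 0) {
  k <- c(k1 = as.numeric(k1), k2 = as.numeric(k2),
         k3 = as.numeric(k3), k4 = as.numeric(k4))
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("rate constants must be finite and >= 0", call. = FALSE)
  }
  structure(k, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Redox mechanism rate constants:\n")
  cat(sprintf("  k1 = %g L mmol^-1 min^-1  (reduction)\n", x[["k1"]]))
  cat(sprintf("  k2 = %g L mmol^-1 min^-1  (reoxidation)\n", x[["k2"]]))
  cat(sprintf("  k3 = %g min^-1            (precipitation)\n", x[["k3"]]))
  cat(sprintf("  k4 = %g mmol L^-1 min^-1  (O2 ingress)\n", x[["k4"]]))
  invisible(x)
}

.state_names <- c("ss", "sh", "red", "ox", "o2", "precipitated")

#' Species concentrations of the redox system
#'
#' A snapshot of all six species tracked by the mechanism, in mmol/L:
#' oxidized protein (`ss`), reduced protein (`sh`), reducing agent (`red`),
#' spent reducing agent (`ox`, phosphine oxide or oxidized DTT), dissolved
#' oxygen (`o2`) and the cumulative precipitated protein pool
#' (`precipitated`, non-reactive).
#'
#' @param ss,sh,red,ox,o2,precipitated concentrations, mmol/L, all >= 0
#' @return an object of class `system_state` (a named numeric vector)
#' @examples
#' system_state(ss = 0.113, red = 18 * 0.113)
#' @export
system_state <- function(ss = 0, sh = 0, red = 0, ox = 0, o2 = 0,
                         precipitated = 0) {
  s <- c(ss = as.numeric(ss), sh = as.numeric(sh), red = as.numeric(red),
         ox = as.numeric(ox), o2 = as.numeric(o2),
         precipitated = as.numeric(precipitated))
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  structure(s, class = "system_state")
}

#' Mass-action time derivatives of the redox mechanism
#'
#' Evaluates the right-hand side of the kinetic ODE system at one state:
#' \deqn{d[SS]/dt = -k_1 [SS][Red] + k_2 [2SH][O_2]}
#' \deqn{d[2SH]/dt = +k_1 [SS][Red] - k_2 [2SH][O_2] - k_3 [2SH]}
#' \deqn{d[Red]/dt = -k_1 [SS][Red], \quad d[Ox]/dt = +k_1 [SS][Red]}
#' \deqn{d[O_2]/dt = -k_2 [2SH][O_2] + k_4}
#' \deqn{d[prec]/dt = +k_3 [2SH]}
#'
#' @param state a [system_state()] (or named vector with the same fields)
#' @param params a [rate_constants()]
#' @return named numeric vector of derivatives, mmol L^-1 min^-1
#' @export
rate_equations <- function(state, params) {
  state <- as_system_state(state)
  params <- as_rate_constants(params)
  v_red  <- params[["k1"]] * state[["ss"]] * state[["red"]]
  v_reox <- params[["k2"]] * state[["sh"]] * state[["o2"]]
  v_prec <- params[["k3"]] * state[["sh"]]
  c(ss  = -v_red + v_reox,
    sh  = v_red - v_reox - v_prec,
    red = -v_red,
    ox  = v_red,
    o2  = -v_reox + params[["k4"]],
    precipitated = v_prec)
}

as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  x <- unlist(x)
  do.call(rate_constants, as.list(x[intersect(names(x), c("k1", "k2", "k3", "k4"))]))
}

as_system_state <- function(x) {
  if (inherits(x, "system_state")) return(x)
  x <- unlist(x)
  do.call(system_state, as.list(x[intersect(names(x), .state_names)]))
}

#' Simulate the redox mechanism on a time grid
#'
#' Integrates [rate_equations()] with the stiff-capable `lsoda` solver from
#' \pkg{deSolve}. The first grid point must be 0 and the returned state at
#' time 0 equals the initial state exactly. Mass conservation
#' (`ss + sh + precipitated` and `red + ox` constant) is guaranteed by the
#' mechanism and holds to integration tolerance.
#'
#' @param params a [rate_constants()]
#' @param initial a [system_state()]
#' @param times strictly increasing time grid, minutes, starting at 0
#' @param o2_sat optional dissolved-oxygen saturation cap, mmol/L; when set,
#'   the zero-order ingress `k4` switches off once `o2 >= o2_sat`
#'   (default `NULL`, no cap)
#' @param rtol,atol relative and absolute integration tolerances
#' @return a `time_course`: a data frame with columns
#'   `time_min, ss, sh, red, ox, o2, precipitated`
#' @examples
#' tc <- simulate_redox(rate_constants(k1 = 8.03e-4),
#'                      system_state(ss = 0.113, red = 2.034),
#'                      times = seq(0, 3300, length.out = 50))
#' head(tc)
#' @export
simulate_redox <- function(params, initial, times, o2_sat = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  params <- as_rate_constants(params)
  initial <- as_system_state(initial)
  times <- as.numeric(times)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing and start at 0", call. = FALSE)
  }
  deriv <- function(t, y, p) {
    k4_eff <- if (!is.null(o2_sat) && y[["o2"]] >= o2_sat) 0 else p[["k4"]]
    v_red  <- p[["k1"]] * y[["ss"]] * y[["red"]]
    v_reox <- p[["k2"]] * y[["sh"]] * y[["o2"]]
    v_prec <- p[["k3"]] * y[["sh"]]
    list(c(-v_red + v_reox,
           v_red - v_reox - v_prec,
           -v_red, v_red,
           -v_reox + k4_eff,
           v_prec))
  }
  y0 <- stats::setNames(as.numeric(initial), .state_names)
  out <- deSolve::lsoda(y = y0, times = times, func = deriv,
                        parms = unclass(params), rtol = rtol, atol = atol)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop(sprintf(
      "ODE integration failed (lsoda istate = %d) near t = %g min; last state: %s",
      diagn[1], max(out[, "time"]),
      paste(sprintf("%s=%.4g", .state_names, out[nrow(out), .state_names]),
            collapse = ", ")), call. = FALSE)
  }
  states <- as.data.frame(out)[, .state_names]
  # lsoda can undershoot 0 by O(atol); clip that, but treat larger
  # negativity as an integration failure rather than silently masking it
  neg_tol <- 100 * atol
  low <- min(as.matrix(states))
  if (low < -neg_tol) {
    stop(sprintf("negative concentration %.3g beyond tolerance during integration",
                 low), call. = FALSE)
  }
  states[states < 0] <- 0
  states[1, ] <- as.numeric(initial)
  tc <- cbind(time_min = times, states)
  structure(tc, class = c("time_course", "data.frame"),
            params = params, initial = initial)
}

#' Closed-form second-order reduction time course
#'
#' Analytic solution of `d[SS]/dt = -k1 [SS][Red]` with
#' `[Red](t) - [SS](t)` constant (reoxidation, precipitation and oxygen
#' ingress all absent). Serves as an independent oracle for the numerical
#' integrator and as a fast forward model for reduction-only fits.
#'
#' For `red0 != ss0`:
#' \deqn{[SS](t) = \frac{ss_0 (red_0 - ss_0)}{red_0 e^{k_1 (red_0 - ss_0) t} - ss_0}}
#' and in the equimolar limit `[SS](t) = ss0 / (1 + k1 ss0 t)`.
#'
#' @param k1 reduction rate constant, L mmol^-1 min^-1
#' @param ss0,red0 initial concentrations, mmol/L
#' @param times minutes
#' @return numeric vector of `[SS]` concentrations, mmol/L
#' @export
ss_second_order <- function(k1, ss0, red0, times) {
  stopifnot(k1 >= 0, ss0 >= 0, red0 >= 0)
  d <- red0 - ss0
  if (abs(d) < 1e-12 * max(ss0, red0, 1)) {
    return(ss0 / (1 + k1 * ss0 * times))
  }
  ss0 * d / (red0 * exp(k1 * d * times) - ss0)
}

#' Half-life of the oxidized species under second-order reduction
#'
#' Time for `[SS]` to fall to half its initial value when only the
#' second-order reduction step operates:
#' \deqn{t_{1/2} = \frac{\ln(2 - c_{SS,0}/c_{Red,0})}{k_1 (c_{Red,0} - c_{SS,0})}}
#' valid for `c_red0 > c_ss0`. When the protein is in excess but by no more
#' than a factor of two, the two concentrations swap roles in both the
#' difference and the fraction. When `c_ss0 > 2 c_red0` the reducing agent is
#' exhausted before `[SS]` can halve and the half-life is undefined
#' (`NA` is returned). At exactly equal concentrations the continuous limit
#' `1/(k1 c_ss0)` applies.
#'
#' @param k1 reduction rate constant, L mmol^-1 min^-1, > 0
#' @param c_ss0 initial oxidized-protein concentration, mmol/L, > 0
#' @param c_red0 initial reducing-agent concentration, mmol/L, > 0
#' @return half-life in minutes, or `NA_real_` when undefined
#' @examples
#' half_life(8.03e-4, 0.113, 18 * 0.113)  # ~431 min
#' @export
half_life <- function(k1, c_ss0, c_red0) {
  if (!is.finite(k1) || k1 <= 0) stop("'k1' must be > 0", call. = FALSE)
  if (!is.finite(c_ss0) || c_ss0 <= 0 || !is.finite(c_red0) || c_red0 <= 0) {
    stop("initial concentrations must be > 0", call. = FALSE)
  }
  rel <- abs(c_red0 - c_ss0) / max(c_red0, c_ss0)
  if (rel < 1e-9) return(1 / (k1 * c_ss0))
  if (c_red0 > c_ss0) {
    log(2 - c_ss0 / c_red0) / (k1 * (c_red0 - c_ss0))
  } else if (c_ss0 <= 2 * c_red0) {
    log(2 - c_red0 / c_ss0) / (k1 * (c_ss0 - c_red0))
  } else {
    NA_real_  # [SS] can never reach half its initial value
  }
}

#' Fraction of soluble protein in the reduced state
#'
#' Returns `sh / (ss + sh)` at each time point of a simulated course. The
#' terminal value is the steady-state conversion rate; with active
#' reoxidation sustained by oxygen ingress it plateaus strictly below 1
#' (incomplete conversion).
#'
#' @param course a `time_course` from [simulate_redox()]
#' @return numeric vector of fractions in `[0, 1]`; time points where no
#'   soluble protein remains give `NA` and are counted in the
#'   `n_undefined` attribute
#' @export
conversion_fraction <- function(course) {
  stopifnot(inherits(course, "time_course"))
  tot <- course$ss + course$sh
  frac <- ifelse(tot > 0, course$sh / tot, NA_real_)
  structure(frac, n_undefined = sum(tot == 0))
}

#' Classify the late-time regime of a redox time course
#'
#' The coupled redox cycle shows three qualitative stages: net reduction
#' (`[SS]` still falling), steady state (reduction and reoxidation balanced),
#' and net reoxidation after the reducing agent is exhausted (`[SS]` rising
#' again). Classification is by the sign of `d[SS]/dt` at the final state.
#'
#' @param course a `time_course`
#' @param tol derivative magnitude below which the system is called
#'   stationary, mmol L^-1 min^-1
#' @return one of `"reduction"`, `"steady_state"`, `"reoxidation"`
#' @export
redox_stage <- function(course, tol = 1e-8) {
  stopifnot(inherits(course, "time_course"))
  params <- attr(course, "params")
  final <- as_system_state(course[nrow(course), .state_names])
  dss <- rate_equations(final, params)[["ss"]]
  if (dss < -tol) "reduction" else if (dss > tol) "reoxidation" else "steady_state"
}
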