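#' Construct an observed concentration-time series
#'
#' Wraps measured (or synthetic) oxidized-protein concentrations against
#' time, together with the experiment metadata the kinetic fit needs: the
#' nominal initial reducing-agent concentration, the temperature and the
#' data source. Small negative readings are tolerated (measurement noise
#' around zero); model states remain nonnegative.
#'
#' @param times minutes, strictly increasing
#' @param ss_obs oxidized protein, mmol/L
#' @param sh_obs optional reduced protein, mmol/L
#' @param source one of `"NMR"`, `"ECD"`, `"synthetic"`
#' @param temperature degrees Celsius
#' @param c_red0 nominal initial reducing-agent concentration, mmol/L
#' @param ss0 nominal initial protein concentration, mmol/L
#'   (default: first `ss_obs` value)
#' @return an `observed_series` data frame
#' @export
observed_series <- function(times, ss_obs, sh_obs = NULL,
                            source = c("synthetic", "NMR", "ECD"),
                            temperature = NA_real_, c_red0, ss0 = ss_obs[1]) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (length(times) < 5) stop("at least 5 points are required", call. = FALSE)
  if (length(ss_obs) != length(times)) stop("length mismatch", call. = FALSE)
  df <- data.frame(time_min = times, ss_obs = as.numeric(ss_obs))
  if (!is.null(sh_obs)) df$sh_obs <- as.numeric(sh_obs)
  structure(df, class = c("observed_series", "data.frame"),
            source = source, temperature = temperature,
            c_red0 = as.numeric(c_red0), ss0 = as.numeric(ss0))
}

# residual vector of one series for a given natural-scale parameter set
.series_residuals <- function(series, pars, rtol, atol) {
  init <- system_state(ss = pars[["ss0"]], red = attr(series, "c_red0"),
                       o2 = pars[["o2_0"]])
  params <- rate_constants(pars[["k1"]], pars[["k2"]], pars[["k3"]], pars[["k4"]])
  times <- series$time_min
  pad <- times[1] != 0
  if (pad) times <- c(0, times)
  tc <- simulate_redox(params, init, times, rtol = rtol, atol = atol)
  if (pad) tc <- tc[-1, ]
  r <- tc$ss - series$ss_obs
  if (!is.null(series$sh_obs)) r <- c(r, tc$sh - series$sh_obs)
  r
}

#' Fit the redox mechanism to observed time courses
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) of the
#' mass-action mechanism against one or more observed series. The objective
#' is the unweighted sum of squared residuals in `[SS]` (plus `[2SH]` where
#' observed). Positive parameters are fitted on the log scale, which
#' enforces positivity and makes the optimum insensitive to the starting
#' point over several orders of magnitude; estimates are reported back on
#' the natural scale.
#'
#' Standard errors come from the Jacobian at the optimum
#' (`sigma^2 (J'J)^{-1}`, delta method back to the natural scale);
#' confidence-interval half-widths use a Student-t quantile with `n - p`
#' degrees of freedom. A parameter whose Jacobian column is numerically
#' null (for example `k1` when the reducing agent is absent) is flagged
#' unidentifiable and reported with an infinite confidence interval.
#'
#' @param series an `observed_series` or list of them
#' @param free character vector naming the free parameters, a subset of
#'   `c("k1","k2","k3","k4","ss0","o2_0")` (default `"k1"`)
#' @param fixed named list overriding default fixed values
#'   (`k2 = k3 = k4 = 0`, `o2_0 = 0`, `ss0` from the series metadata)
#' @param start named list of starting values for free parameters; a crude
#'   initial-slope estimate of `k1` is used when omitted
#' @param level confidence level (default 0.95)
#' @param multi_start number of additional log-spaced starting points spread
#'   over a factor of 100 either side of `start` (default 0); the best
#'   optimum is kept and the spread across optima is recorded
#' @param rtol,atol integration tolerances passed to [simulate_redox()]
#' @return a `redox_fit` object: estimates, standard errors, CI half-widths,
#'   relative SD (percent), SSE, residuals, dof and identifiability flags
#' @examples
#' syn <- synth_time_course(synthetic_design(
#'   truth = rate_constants(k1 = 1e-3), ss0 = 1, red0 = 2,
#'   t_end_min = 2000, n_points = 20, noise_sigma = 0))
#' fit_mechanism(syn$series)
#' @export
fit_mechanism <- function(series, free = "k1", fixed = list(), start = list(),
                          level = 0.95, multi_start = 0,
                          rtol = 1e-8, atol = 1e-10) {
  if (inherits(series, "observed_series")) series <- list(series)
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, TRUE, "observed_series")))
  all_names <- c("k1", "k2", "k3", "k4", "ss0", "o2_0")
  free <- match.arg(free, all_names, several.ok = TRUE)
  if (length(free) == 0) stop("'free' must name at least one parameter", call. = FALSE)

  base <- list(k1 = 1e-3, k2 = 0, k3 = 0, k4 = 0,
               ss0 = attr(series[[1]], "ss0"), o2_0 = 0)
  base[names(fixed)] <- fixed

  n_points <- sum(vapply(series, function(s) {
    nrow(s) * (1 + !is.null(s$sh_obs))
  }, 0))
  p <- length(free)
  if (n_points <= p + 1) stop("too few points for the requested fit", call. = FALSE)

  # crude k1 start from the pseudo-first-order initial slope
  default_start <- base
  if ("k1" %in% free && is.null(start$k1)) {
    s1 <- series[[1]]
    i <- max(2, min(5, nrow(s1)))
    drop <- (s1$ss_obs[1] - s1$ss_obs[i])
    slope <- max(drop, 1e-6 * s1$ss_obs[1]) / (s1$time_min[i] - s1$time_min[1])
    default_start$k1 <- slope / max(s1$ss_obs[1] * attr(s1, "c_red0"), 1e-12)
  }
  for (nm in free) {
    if (!is.null(start[[nm]])) default_start[[nm]] <- start[[nm]]
    if (default_start[[nm]] <= 0) default_start[[nm]] <- 1e-4
  }

  big_resid <- function() rep(1e6, n_points)
  resid_fun <- function(theta_log) {
    vals <- exp(theta_log)
    if (any(!is.finite(vals))) return(big_resid())
    pars <- base
    pars[free] <- vals
    tryCatch(
      unlist(lapply(series, .series_residuals, pars = pars,
                    rtol = rtol, atol = atol)),
      error = function(e) big_resid())
  }

  run_lm <- function(theta0) {
    minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  }

  theta0 <- log(unlist(default_start[free]))
  fits <- list(run_lm(theta0))
  if (multi_start > 0) {
    offs <- seq(-log(100), log(100), length.out = multi_start)
    for (o in offs) fits <- c(fits, list(run_lm(theta0 + o)))
  }
  dev <- vapply(fits, stats::deviance, 0)
  best <- fits[[which.min(dev)]]
  if (best$info == 0 || best$info > 4) {
    stop(sprintf("Levenberg-Marquardt did not converge (info = %d); last iterate: %s",
                 best$info,
                 paste(sprintf("%s=%.4g", free, exp(best$par)), collapse = ", ")),
         call. = FALSE)
  }
  theta_hat <- best$par
  est <- exp(theta_hat)
  names(est) <- free
  sse <- stats::deviance(best)
  dof <- n_points - p
  sigma2 <- sse / dof

  # central-difference Jacobian of residuals w.r.t. log-parameters
  J <- matrix(0, n_points, p)
  h <- 1e-5
  for (j in seq_len(p)) {
    up <- theta_hat; up[j] <- up[j] + h
    dn <- theta_hat; dn[j] <- dn[j] - h
    J[, j] <- (resid_fun(up) - resid_fun(dn)) / (2 * h)
  }
  sv <- svd(J)
  scale_ref <- max(sv$d, sqrt(sum(resid_fun(theta_hat)^2)), .Machine$double.eps)
  identifiable <- rep(TRUE, p)
  se_log <- rep(Inf, p)
  col_norms <- sqrt(colSums(J^2))
  null_col <- col_norms < 1e-8 * max(scale_ref, 1)
  ok <- sv$d > 1e-10 * max(sv$d)
  if (all(ok) && !any(null_col)) {
    cov_log <- sigma2 * crossprod(t(sv$v) / sv$d)
    se_log <- sqrt(pmax(diag(cov_log), 0))
  } else {
    identifiable <- !null_col
    if (any(!null_col)) {
      Jr <- J[, !null_col, drop = FALSE]
      g <- tryCatch(solve(crossprod(Jr)), error = function(e) NULL)
      if (!is.null(g)) se_log[!null_col] <- sqrt(pmax(diag(sigma2 * g), 0))
    }
  }
  se <- se_log * est                        # delta method: d(exp x) = exp(x) dx
  tcrit <- stats::qt(1 - (1 - level) / 2, dof)
  ci_half <- tcrit * se
  rel_sd <- ifelse(est > 0, 100 * se / est, NA_real_)

  # multi-start spread diagnostic (relative range of each estimate)
  spread <- NULL
  if (multi_start > 0) {
    conv <- vapply(fits, function(f) f$info >= 1 && f$info <= 4, TRUE)
    mat <- vapply(fits[conv], function(f) exp(f$par), numeric(p))
    mat <- matrix(mat, nrow = p)
    spread <- apply(mat, 1, function(v) (max(v) - min(v)) / max(v))
    names(spread) <- free
  }

  structure(list(
    estimates = est, standard_errors = se, ci_half_widths = ci_half,
    relative_sd_percent = rel_sd, sse = sse,
    n_points = n_points, n_params = p, dof = dof, level = level,
    residuals = best$fvec, identifiable = stats::setNames(identifiable, free),
    fixed = base[setdiff(all_names, free)], free = free,
    multi_start_spread = spread, info = best$info
  ), class = "redox_fit")
}

#' @export
print.redox_fit <- function(x, ...) {
  cat(sprintf("Redox mechanism fit: %d points, %d parameter(s), SSE = %.4g\n",
              x$n_points, x$n_params, x$sse))
  tab <- data.frame(
    estimate = x$estimates, std_error = x$standard_errors,
    ci_half_width = x$ci_half_widths, rel_sd_pct = x$relative_sd_percent,
    identifiable = x$identifiable)
  print(tab, digits = 4)
  if (any(!x$identifiable)) {
    cat("note: parameters flagged unidentifiable have infinite CIs\n")
  }
  invisible(x)
}

#' Write a fit report
#'
#' Writes a human-readable parameter table and a machine-readable key-value
#' file next to it.
#'
#' @param fit a `redox_fit`
#' @param path base file path; `<path>.txt` and `<path>.tsv` are written
#' @return invisibly, the two file paths
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "redox_fit"))
  txt <- file.path(paste0(path, ".txt"))
  tsv <- file.path(paste0(path, ".tsv"))
  con <- file(txt, "w"); on.exit(close(con))
  writeLines(utils::capture.output(print(fit)), con)
  tab <- data.frame(parameter = fit$free, estimate = fit$estimates,
                    std_error = fit$standard_errors,
                    ci_half_width = fit$ci_half_widths,
                    rel_sd_pct = fit$relative_sd_percent,
                    identifiable = fit$identifiable)
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(txt, tsv))
}

# R^2 in the fitted (log) space; a perfectly flat response counts as exact
.r_squared <- function(fit) {
  y <- fit$model[[1]]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / tss))
}

#' Arrhenius activation energy from rate constants at several temperatures
#'
#' Ordinary least squares of `ln k1` against `1/T` (T in kelvin,
#' `T = degC + 273.15`); the activation energy is `-slope * R` with
#' `R = 8.314 J mol^-1 K^-1`, reported in kJ/mol.
#'
#' @param temperature_c temperatures, degrees Celsius (distinct)
#' @param k1 rate constants, L mmol^-1 min^-1, > 0
#' @return an `arrhenius_fit` list: `ea_kj_mol`, `ln_preexponential`,
#'   `r_squared`
#' @examples
#' arrhenius_fit(c(15, 25, 37), c(3.05e-4, 7.68e-4, 1.15e-3))
#' @export
arrhenius_fit <- function(temperature_c, k1) {
  stopifnot(length(temperature_c) == length(k1), length(k1) >= 2)
  if (anyDuplicated(temperature_c)) {
    stop("temperatures must be distinct", call. = FALSE)
  }
  if (any(k1 <= 0)) stop("'k1' must be > 0", call. = FALSE)
  inv_t <- 1 / (temperature_c + 273.15)
  fit <- stats::lm(log(k1) ~ inv_t)
  r2 <- .r_squared(fit)
  structure(list(ea_kj_mol = -unname(stats::coef(fit)[2]) * 8.314 / 1000,
                 ln_preexponential = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.2f kJ/mol, ln A = %.3f, R^2 = %.3f\n",
              x$ea_kj_mol, x$ln_preexponential, x$r_squared))
  invisible(x)
}

#' Exponential dependence of reduction half-life on outer helix length
#'
#' Fits `t_1/2 = a * exp(b * n)` by ordinary least squares of `ln t_1/2`
#' against `n`, the number of residues N-terminal of the first cysteine
#' ("outer helix length"). R-squared is computed in log space.
#'
#' @param n_residues outer helix lengths (counts, >= 0)
#' @param t_half half-lives, minutes, > 0
#' @return an `exp_length_fit` list: `a_min`, `b_per_residue`, `r_squared`
#' @examples
#' helix_length_fit(c(17, 9, 3, 0), c(909, 67, 14, 1))   # TCEP series
#' @export
helix_length_fit <- function(n_residues, t_half) {
  stopifnot(length(n_residues) == length(t_half))
  if (length(t_half) < 3) stop("at least 3 points are required", call. = FALSE)
  if (any(t_half <= 0)) stop("'t_half' must be > 0", call. = FALSE)
  fit <- stats::lm(log(t_half) ~ n_residues)
  structure(list(a_min = exp(unname(stats::coef(fit)[1])),
                 b_per_residue = unname(stats::coef(fit)[2]),
                 r_squared = .r_squared(fit)),
            class = "exp_length_fit")
}

#' @export
print.exp_length_fit <- function(x, ...) {
  cat(sprintf("t_1/2 = %.3f min * exp(%.4f * n), R^2 = %.3f\n",
              x$a_min, x$b_per_residue, x$r_squared))
  invisible(x)
}

#' Extrapolate a half-life from the helix-length regression
#'
#' @param fit an `exp_length_fit`
#' @param n outer helix length, residues, >= 0
#' @return predicted half-life, minutes
#' @examples
#' f <- helix_length_fit(c(9, 3, 0), c(1659, 115, 62))   # DTT series
#' extrapolate_half_life(f, 17)
#' @export
extrapolate_half_life <- function(fit, n) {
  stopifnot(inherits(fit, "exp_length_fit"), n >= 0)
  fit$a_min * exp(fit$b_per_residue * n)
}
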