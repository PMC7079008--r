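#' Ensemble of CD spectra on a shared wavelength grid
#'
#' @param wavelengths nm, strictly increasing
#' @param matrix mean-residue molar ellipticity, one column per spectrum
#' @param labels data frame with one row per spectrum, columns `variant`
#'   and `temperature_c` (optional; defaults are generated)
#' @return a `spectrum_set`
#' @export
spectrum_set <- function(wavelengths, matrix, labels = NULL) {
  matrix <- as.matrix(matrix)
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) {
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  }
  if (nrow(matrix) != length(wavelengths)) stop("dimension mismatch", call. = FALSE)
  if (ncol(matrix) < 2) stop("at least 2 spectra are required", call. = FALSE)
  if (any(!is.finite(matrix))) stop("missing/non-finite ellipticity values", call. = FALSE)
  if (is.null(labels)) {
    labels <- data.frame(variant = sprintf("s%02d", seq_len(ncol(matrix))),
                         temperature_c = NA_real_)
  }
  stopifnot(nrow(labels) == ncol(matrix))
  structure(list(wavelengths = wavelengths, matrix = matrix, labels = labels),
            class = "spectrum_set")
}

# least squares of y ~ C w with w on the probability simplex.
# Small component counts only: enumerate support sets, solve the
# equality-constrained problem on each, keep the feasible minimum.
simplex_lsq <- function(C, y) {
  k <- ncol(C)
  best_w <- NULL
  best_r <- Inf
  supports <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  for (S in supports) {
    ks <- length(S)
    Cs <- C[, S, drop = FALSE]
    # KKT system for min ||y - Cs w||^2 s.t. sum(w) = 1
    A <- rbind(cbind(2 * crossprod(Cs), rep(1, ks)), c(rep(1, ks), 0))
    b <- c(2 * crossprod(Cs, y), 1)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) next
    w_s <- sol[seq_len(ks)]
    if (any(w_s < -1e-10)) next
    w <- numeric(k)
    w[S] <- pmax(w_s, 0)
    w <- w / sum(w)
    r <- sum((y - C %*% w)^2)
    if (r < best_r - 1e-15) {
      best_r <- r
      best_w <- w
    }
  }
  best_w
}

#' Convex factorization of a CD spectrum ensemble
#'
#' Decomposes an ensemble of spectra into `n_components` pure component
#' curves and per-spectrum convex mixing weights by alternating constrained
#' least squares: the weights step solves, for each spectrum, a least-squares
#' problem constrained to the probability simplex (weights >= 0, summing
#' to 1); the components step solves an unconstrained least-squares problem
#' per wavelength. Each step solves its subproblem exactly, so the squared
#' reconstruction error is non-increasing across iterations.
#'
#' Components are initialized from the pair (or greedy farthest set) of
#' input spectra with maximal Euclidean separation, and on output are
#' ordered by their ellipticity at 222 nm, most negative first: the helical,
#' folded "C-type" curve has a strongly negative 222 nm band, the unfolded
#' "U-type" curve does not.
#'
#' Ensembles whose numerical rank is below `n_components` (for example, all
#' spectra identical) have non-unique weights; the factorization proceeds
#' via a pseudoinverse and the result carries `degenerate = TRUE` along
#' with a warning.
#'
#' @param data a [spectrum_set()]
#' @param n_components number of pure components (default 2)
#' @param tol relative SSE change below which iteration stops
#' @param max_iter iteration cap
#' @return an `ecd_deconv`: `components` (wavelength x component matrix),
#'   `weights` (component x spectrum matrix), `sse`, `n_iter`, `sse_path`,
#'   `degenerate`, plus the wavelengths and labels of the input
#' @export
deconvolve_spectra <- function(data, n_components = 2, tol = 1e-8,
                               max_iter = 1000) {
  stopifnot(inherits(data, "spectrum_set"))
  Y <- data$matrix
  m <- ncol(Y)
  k <- as.integer(n_components)
  if (k < 1 || k >= m) {
    stop("'n_components' must be at least 1 and below the number of spectra",
         call. = FALSE)
  }
  sv_data <- svd(Y, nu = 0, nv = 0)$d
  rank_y <- sum(sv_data > max(dim(Y)) * .Machine$double.eps * sv_data[1])
  degenerate <- rank_y < k
  if (degenerate) {
    warning(sprintf(
      "ensemble rank (%d) is below n_components (%d): weights are not unique; consider fewer components",
      rank_y, k), call. = FALSE)
  }

  # farthest-point column initialization
  d2 <- as.matrix(stats::dist(t(Y)))
  pick <- as.integer(arrayInd(which.max(d2), dim(d2)))
  while (length(pick) < k) {
    rest <- setdiff(seq_len(m), pick)
    score <- apply(d2[rest, pick, drop = FALSE], 1, min)
    pick <- c(pick, rest[which.max(score)])
  }
  C <- Y[, pick[seq_len(k)], drop = FALSE]

  W <- matrix(0, k, m)
  sse_path <- numeric(0)
  sse_prev <- Inf
  iter <- 0
  pinv <- function(A) {
    s <- svd(A)
    ok <- s$d > max(dim(A)) * .Machine$double.eps * max(s$d, 1e-300)
    if (!any(ok)) return(matrix(0, ncol(A), nrow(A)))
    s$v[, ok, drop = FALSE] %*% (t(s$u[, ok, drop = FALSE]) / s$d[ok])
  }
  repeat {
    iter <- iter + 1
    for (j in seq_len(m)) W[, j] <- simplex_lsq(C, Y[, j])
    C <- Y %*% t(W) %*% pinv(tcrossprod(W))
    sse <- sum((Y - C %*% W)^2)
    if (length(sse_path) > 0 && sse > sse_path[length(sse_path)] * (1 + 1e-9) + 1e-12) {
      stop("internal error: SSE increased across an ALS iteration", call. = FALSE)
    }
    sse_path <- c(sse_path, sse)
    if (iter >= max_iter) break
    if (is.finite(sse_prev) &&
        (sse_prev - sse) <= tol * max(sse_prev, .Machine$double.eps)) break
    sse_prev <- sse
  }

  # order: folded component (most negative 222 nm ellipticity) first
  ref_idx <- which.min(abs(data$wavelengths - 222))
  ord <- order(C[ref_idx, ])
  C <- C[, ord, drop = FALSE]
  W <- W[ord, , drop = FALSE]
  colnames(C) <- rownames(W) <- paste0("component", seq_len(k))

  structure(list(components = C, weights = W, sse = sse, n_iter = iter,
                 sse_path = sse_path, degenerate = degenerate,
                 wavelengths = data$wavelengths, labels = data$labels),
            class = "ecd_deconv")
}

#' @export
print.ecd_deconv <- function(x, ...) {
  cat(sprintf(
    "Convex spectral factorization: %d components, %d spectra, SSE = %.4g (%d iterations)%s\n",
    ncol(x$components), ncol(x$weights), x$sse, x$n_iter,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Folded fraction per spectrum
#'
#' Percentage weight of the folded-ordered component (the first component,
#' i.e. the one with the most negative 222 nm ellipticity) in each spectrum.
#'
#' @param result an `ecd_deconv`
#' @return data frame: `variant`, `temperature_c`, `folded_pct`
#' @export
folded_fraction <- function(result) {
  stopifnot(inherits(result, "ecd_deconv"))
  out <- result$labels
  out$folded_pct <- 100 * result$weights[1, ]
  out
}
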