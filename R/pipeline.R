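#' Run a configured analysis pipeline stage
#'
#' Config-driven orchestration of the package's stages. The configuration
#' (a YAML file or an equivalent named list) holds one block per stage plus
#' optional globals (`outdir`, `seed`, `verbose`). Every run writes a log
#' (inputs, package version, seed, tolerances) and machine-readable result
#' files to `outdir`; identical config and seed give identical result files.
#'
#' Supported stages and their block keys:
#' \describe{
#'   \item{simulate}{`k1..k4, ss0, red0, o2_0, t_end_min, n_points` ->
#'     `time_course.csv`}
#'   \item{fit}{`series` (path) or inline `synth` block, `free`, `fixed` ->
#'     `fit_report.txt/.tsv`}
#'   \item{halflife}{`k1, c_ss0, c_red0` -> `half_life.txt`}
#'   \item{arrhenius}{`table` (path with `temperature_c,k1`) or inline
#'     `temperature_c`, `k1` -> `arrhenius.txt`}
#'   \item{lengthfit}{`n`, `t_half` (or `table` path), optional
#'     `extrapolate` -> `length_fit.txt`}
#'   \item{deconv}{`spectra` (path), `n_components` -> components/weights}
#'   \item{descriptors}{`table` (path `variant,n_outer,rmsd_outer,helicity`)
#'     -> `descriptors.csv`}
#'   \item{synth}{[synthetic_design()] fields -> series + raw tables + truth}
#' }
#'
#' @param config path to a YAML file or a named list
#' @param stage stage name; default: the single stage block present
#' @param outdir output directory (overrides the config global)
#' @return invisibly, a named list of written file paths and key results
#' @export
run_pipeline <- function(config, stage = NULL, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages <- c("simulate", "fit", "halflife", "arrhenius", "lengthfit",
              "deconv", "descriptors", "synth")
  if (is.null(stage)) {
    present <- intersect(stages, names(config))
    if (length(present) != 1) {
      stop(sprintf("specify 'stage'; config contains: %s",
                   paste(present, collapse = ", ")), call. = FALSE)
    }
    stage <- present
  }
  stage <- match.arg(stage, stages)
  blk <- config[[stage]]
  if (is.null(blk)) {
    stop(sprintf("config has no '%s' block", stage), call. = FALSE)
  }
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) outdir <- "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  log_lines <- c(sprintf("redoxkin %s | stage: %s | seed: %s",
                         as.character(utils::packageVersion("redoxkin")),
                         stage, if (is.null(seed)) "none" else seed),
                 sprintf("run at: %s", format(Sys.time())),
                 sprintf("config: %s", paste(deparse(blk), collapse = " ")))

  num <- function(x, default = 0) if (is.null(x)) default else as.numeric(x)

  if (stage == "simulate") {
    params <- rate_constants(num(blk$k1), num(blk$k2), num(blk$k3), num(blk$k4))
    init <- system_state(ss = num(blk$ss0), red = num(blk$red0),
                         o2 = num(blk$o2_0))
    times <- seq(0, num(blk$t_end_min, 1000), length.out = num(blk$n_points, 100))
    tc <- simulate_redox(params, init, times)
    p <- file.path(outdir, "time_course.csv")
    write_time_course(tc, p)
    results$time_course <- p
  } else if (stage == "synth") {
    design <- synthetic_design(
      truth = rate_constants(num(blk$k1, 8.03e-4), num(blk$k2), num(blk$k3),
                             num(blk$k4)),
      ss0 = num(blk$ss0, 0.113), red0 = num(blk$red0, 18 * 0.113),
      o2_0 = num(blk$o2_0), t_end_min = num(blk$t_end_min, 3300),
      n_points = num(blk$n_points, 40),
      spacing = if (is.null(blk$spacing)) "log" else blk$spacing,
      noise_sigma = num(blk$noise_sigma, 0.02),
      seed = if (num(blk$noise_sigma, 0.02) > 0) {
        if (!is.null(blk$seed)) as.integer(blk$seed) else as.integer(seed)
      } else NULL)
    syn <- synth_time_course(design)
    p <- file.path(outdir, "synthetic_series.csv")
    write_observed_series(syn$series, p)
    tp <- file.path(outdir, "synthetic_truth.txt")
    write_truth_sidecar(syn$truth, tp)
    results$series <- p
    results$truth <- tp
    if (!is.null(syn$integrals)) {
      ip <- file.path(outdir, "synthetic_integrals.csv")
      utils::write.csv(syn$integrals, ip, row.names = FALSE, quote = FALSE)
      results$integrals <- ip
    }
  } else if (stage == "fit") {
    series <- read_observed_series(blk$series)
    free <- if (is.null(blk$free)) "k1" else unlist(blk$free)
    fit <- fit_mechanism(series, free = free,
                         fixed = if (is.null(blk$fixed)) list() else blk$fixed)
    base <- file.path(outdir, "fit_report")
    write_fit_report(fit, base)
    results$fit <- fit
    results$report <- paste0(base, c(".txt", ".tsv"))
  } else if (stage == "halflife") {
    hl <- half_life(num(blk$k1), num(blk$c_ss0), num(blk$c_red0))
    p <- file.path(outdir, "half_life.txt")
    writeLines(sprintf("t_half_min: %s",
                       if (is.na(hl)) "undefined" else format(hl)), p)
    results$half_life <- hl
    results$file <- p
  } else if (stage == "arrhenius") {
    if (!is.null(blk$table)) {
      tab <- utils::read.csv(blk$table)
      tc_ <- tab$temperature_c; kk <- tab$k1
    } else {
      tc_ <- as.numeric(unlist(blk$temperature_c))
      kk <- as.numeric(unlist(blk$k1))
    }
    fit <- arrhenius_fit(tc_, kk)
    p <- file.path(outdir, "arrhenius.txt")
    writeLines(c(sprintf("ea_kj_mol: %.10g", fit$ea_kj_mol),
                 sprintf("ln_preexponential: %.10g", fit$ln_preexponential),
                 sprintf("r_squared: %.10g", fit$r_squared)), p)
    results$arrhenius <- fit
    results$file <- p
  } else if (stage == "lengthfit") {
    if (!is.null(blk$table)) {
      tab <- utils::read.csv(blk$table)
      nn <- tab$n; tt <- tab$t_half
    } else {
      nn <- as.numeric(unlist(blk$n)); tt <- as.numeric(unlist(blk$t_half))
    }
    fit <- helix_length_fit(nn, tt)
    lines <- c(sprintf("a_min: %.10g", fit$a_min),
               sprintf("b_per_residue: %.10g", fit$b_per_residue),
               sprintf("r_squared: %.10g", fit$r_squared))
    if (!is.null(blk$extrapolate)) {
      ex <- extrapolate_half_life(fit, as.numeric(blk$extrapolate))
      lines <- c(lines, sprintf("extrapolated_t_half_at_n%s: %.10g",
                                blk$extrapolate, ex))
      results$extrapolated <- ex
    }
    p <- file.path(outdir, "length_fit.txt")
    writeLines(lines, p)
    results$length_fit <- fit
    results$file <- p
  } else if (stage == "deconv") {
    data <- read_spectrum_set(blk$spectra)
    res <- deconvolve_spectra(data, n_components = num(blk$n_components, 2))
    base <- file.path(outdir, "deconv")
    write_deconv_result(res, base)
    results$deconv <- res
    results$files <- paste0(base, c("_components.csv", "_weights.csv"))
  } else if (stage == "descriptors") {
    tab <- helix_descriptors(utils::read.csv(blk$table))
    p <- file.path(outdir, "descriptors.csv")
    utils::write.csv(tab, p, row.names = FALSE, quote = FALSE)
    results$descriptors <- tab
    results$file <- p
  }

  log_path <- file.path(outdir, sprintf("%s.log", stage))
  writeLines(log_lines, log_path)
  results$log <- log_path
  invisible(results)
}
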