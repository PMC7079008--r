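#' Write a simulated time course as delimited text
#'
#' Header: `time_min,ss,sh,red,ox,o2,precipitated`.
#'
#' @param course a `time_course`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_time_course <- function(course, path) {
  stopifnot(inherits(course, "time_course"))
  utils::write.csv(as.data.frame(course), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time course written by [write_time_course()]
#' @param path input file
#' @return a data frame
#' @export
read_time_course <- function(path) {
  utils::read.csv(path)
}

#' Write an observed series with metadata header lines
#'
#' Metadata (`source`, `temperature`, `c_red0`, `ss0`) is stored in
#' commented `# key: value` lines above a `time_min,ss_mM[,sh_mM]` table.
#'
#' @param series an [observed_series()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_observed_series <- function(series, path) {
  stopifnot(inherits(series, "observed_series"))
  con <- file(path, "w"); on.exit(close(con))
  for (key in c("source", "temperature", "c_red0", "ss0")) {
    writeLines(sprintf("# %s: %s", key, format(attr(series, key))), con)
  }
  df <- data.frame(time_min = series$time_min, ss_mM = series$ss_obs)
  if (!is.null(series$sh_obs)) df$sh_mM <- series$sh_obs
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observed series written by [write_observed_series()]
#' @param path input file
#' @return an [observed_series()]
#' @export
read_observed_series <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(key)]] <- val
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  observed_series(df$time_min, df$ss_mM,
                  sh_obs = if ("sh_mM" %in% names(df)) df$sh_mM else NULL,
                  source = if (!is.null(meta$source)) meta$source else "synthetic",
                  temperature = as.numeric(meta$temperature),
                  c_red0 = as.numeric(meta$c_red0),
                  ss0 = if (!is.null(meta$ss0)) as.numeric(meta$ss0) else df$ss_mM[1])
}

#' Write a spectrum ensemble as a delimited matrix
#'
#' First column `wavelength_nm`, remaining columns named
#' `<variant>@<temperature>C`.
#'
#' @param data a [spectrum_set()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_spectrum_set <- function(data, path) {
  stopifnot(inherits(data, "spectrum_set"))
  df <- data.frame(wavelength_nm = data$wavelengths, data$matrix,
                   check.names = FALSE)
  names(df)[-1] <- sprintf("%s@%sC", data$labels$variant,
                           format(data$labels$temperature_c, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum ensemble written by [write_spectrum_set()]
#' @param path input file
#' @return a [spectrum_set()]
#' @export
read_spectrum_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- names(df)[-1]
  variant <- sub("@.*$", "", cols)
  temp <- suppressWarnings(as.numeric(sub("C$", "", sub("^.*@", "", cols))))
  spectrum_set(df[[1]], as.matrix(df[, -1, drop = FALSE]),
               data.frame(variant = variant, temperature_c = temp))
}

#' Write a deconvolution result as two delimited files
#'
#' `<path>_components.csv` holds the pure spectra (wavelength plus one
#' column per component); `<path>_weights.csv` the per-spectrum convex
#' weights with variant and temperature columns.
#'
#' @param result an `ecd_deconv`
#' @param path base path (no extension)
#' @return invisibly, the two file paths
#' @export
write_deconv_result <- function(result, path) {
  stopifnot(inherits(result, "ecd_deconv"))
  comp_path <- paste0(path, "_components.csv")
  wt_path <- paste0(path, "_weights.csv")
  utils::write.csv(data.frame(wavelength_nm = result$wavelengths,
                              result$components, check.names = FALSE),
                   comp_path, row.names = FALSE, quote = FALSE)
  wt <- cbind(result$labels, as.data.frame(t(result$weights)))
  utils::write.csv(wt, wt_path, row.names = FALSE, quote = FALSE)
  invisible(c(comp_path, wt_path))
}

#' Write a ground-truth sidecar file
#'
#' Key-value lines recording the true parameters of a synthetic dataset.
#'
#' @param truth named vector or list
#' @param path output file
#' @return invisibly, `path`
#' @export
write_truth_sidecar <- function(truth, path) {
  vals <- unlist(truth)
  writeLines(sprintf("%s: %.17g", names(vals), vals), path)
  invisible(path)
}
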