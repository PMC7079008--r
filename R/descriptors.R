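#' Steric factor of the outer helical segment
#'
#' Composite descriptor rationalizing why longer, bulkier and less helical
#' N-terminal segments shield the disulfide from the reducing agent:
#' \deqn{x = \frac{n \times RMSD}{[\sum CSD_{H\alpha}(i)]/i}}
#' i.e. outer helix length times its backbone RMSD divided by its mean
#' per-residue H-alpha chemical-shift deviation (helicity). By convention
#' `x = 0` for a variant with no outer segment (`n_outer = 0`).
#'
#' @param n_outer residues N-terminal of the first cysteine (count, >= 0)
#' @param rmsd_outer backbone RMSD of the outer segment, Angstrom, >= 0
#' @param helicity mean per-residue H-alpha CSD, ppm; must be > 0 when
#'   `n_outer > 0`
#' @return dimensionless steric factor (vectorized)
#' @examples
#' steric_factor(9, 0.55, 0.26)    # ~19.0
#' steric_factor(0, 0, 0)          # 0 by convention
#' @export
steric_factor <- function(n_outer, rmsd_outer, helicity) {
  stopifnot(all(n_outer >= 0), all(rmsd_outer >= 0))
  bad <- n_outer > 0 & (!is.finite(helicity) | helicity <= 0)
  if (any(bad)) {
    stop("helicity must be > 0 when n_outer > 0", call. = FALSE)
  }
  ifelse(n_outer == 0, 0, n_outer * rmsd_outer / helicity)
}

#' Mean per-residue chemical-shift deviation
#'
#' Average of absolute H-alpha chemical-shift deviations over a helical
#' segment; higher values indicate a more structured helix. Signs of the
#' raw deviations are dropped (absolute-value convention).
#'
#' @param values per-residue H-alpha CSDs, ppm (non-empty)
#' @return mean absolute CSD, ppm
#' @export
mean_csd <- function(values) {
  if (length(values) == 0) stop("empty CSD list", call. = FALSE)
  mean(abs(values))
}

# the nine diagnostic cage protons of the Trp-cage core
.cage_protons <- data.frame(
  residue = c("W25", "L26", "G30", "P31", "R35", "P37", "P37", "P38", "P38"),
  atom    = c("HE1", "HA", "HA2", "HB2", "HA", "HA", "HB2", "HD1", "HD2"),
  stringsAsFactors = FALSE)

#' Cage compactness score from chemical-shift deviations
#'
#' Sums the absolute CSDs of the nine diagnostic protons of the Trp-cage
#' hydrophobic core (W25 HE1, L26 HA, G30 HA2, P31 HB2, R35 HA, P37 HA,
#' P37 HB2, P38 HD1, P38 HD2). All nine must be present.
#'
#' @param table data frame with columns `residue`, `atom`, `csd_ppm`
#' @return dimensionless cage score
#' @examples
#' tab <- cage_proton_table()
#' tab$csd_ppm <- 1.3
#' csd_cage(tab)    # 11.7
#' @export
csd_cage <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("residue", "atom", "csd_ppm") %in% names(table)))
  key <- paste(table$residue, table$atom)
  want <- paste(.cage_protons$residue, .cage_protons$atom)
  miss <- setdiff(want, key)
  if (length(miss) > 0) {
    stop(sprintf("missing cage proton(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  vals <- table$csd_ppm[match(want, key)]
  if (any(!is.finite(vals))) stop("non-finite CSD value", call. = FALSE)
  sum(abs(vals))
}

#' Template table of the nine cage protons
#'
#' @return data frame with `residue`, `atom` and an `csd_ppm` column of NAs,
#'   one row per diagnostic cage proton
#' @export
cage_proton_table <- function() {
  out <- .cage_protons
  out$csd_ppm <- NA_real_
  out
}

#' Helix descriptors for a set of variants
#'
#' Convenience wrapper computing the steric factor for a descriptor table.
#'
#' @param table data frame with columns `variant`, `n_outer`, `rmsd_outer`,
#'   `helicity`
#' @return the table with a `steric_factor` column appended
#' @export
helix_descriptors <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("variant", "n_outer", "rmsd_outer", "helicity") %in% names(table)))
  table$steric_factor <- steric_factor(table$n_outer, table$rmsd_outer,
                                       table$helicity)
  table
}
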