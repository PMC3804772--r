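#' Thermodynamic constants for free-energy / dissociation-constant conversion
#'
#' Bundles the gas constant and absolute temperature used throughout the
#' package in the relation \eqn{\Delta G = RT \ln K_D}.  Defaults follow the
#' convention used for tubulin-binding affinity tables: R = 0.00199
#' kcal/(mol K) and T = 298 K.
#'
#' @param gas_constant_R Gas constant in kcal mol^-1 K^-1. Must be positive.
#' @param temperature_T Absolute temperature in kelvin. Must be positive.
#'
#' @return An object of class `thermo_constants`: a list with elements
#'   `gas_constant_R` and `temperature_T`.
#' @examples
#' thermo_constants()
#' thermo_constants(temperature_T = 310)
#' @export
thermo_constants <- function(gas_constant_R = 0.00199, temperature_T = 298) {
  if (!is.numeric(gas_constant_R) || length(gas_constant_R) != 1L ||
      !is.finite(gas_constant_R) || gas_constant_R <= 0) {
    stop("`gas_constant_R` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(temperature_T) || length(temperature_T) != 1L ||
      !is.finite(temperature_T) || temperature_T <= 0) {
    stop("`temperature_T` must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(gas_constant_R = gas_constant_R, temperature_T = temperature_T),
    class = "thermo_constants"
  )
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("Thermodynamic constants: R =", x$gas_constant_R,
      "kcal/(mol K), T =", x$temperature_T, "K\n")
  invisible(x)
}

# micromolar -> molar inside the logarithm; fixed convention, all K_D I/O is in uM
.UM_TO_M <- 1e-6

#' Binding free energy from a dissociation constant
#'
#' Computes \eqn{\Delta G_{bind} = RT \ln K_D} with `kd` given in micromolar
#' and converted to mol/L inside the logarithm.  With the default constants a
#' K_D below 1 M gives a negative free energy; the function is strictly
#' increasing in `kd`.
#'
#' @param kd Dissociation constant(s) in micromolar. Must be positive.
#' @param constants A [thermo_constants()] object.
#' @param compound_id Optional label(s) used in error messages when a
#'   non-positive `kd` is encountered.
#'
#' @return Binding free energy in kcal/mol (vectorised over `kd`).
#' @seealso [kd_from_dg()] for the inverse.
#' @examples
#' dg_from_kd(38)   # ~ -6.036 kcal/mol
#' dg_from_kd(1e6)  # 1 M: exactly 0
#' @export
dg_from_kd <- function(kd, constants = thermo_constants(), compound_id = NULL) {
  stopifnot(inherits(constants, "thermo_constants"))
  if (!is.numeric(kd)) stop("`kd` must be numeric (micromolar)", call. = FALSE)
  bad <- !is.na(kd) & (!is.finite(kd) | kd <= 0)
  if (any(bad)) {
    who <- if (!is.null(compound_id)) {
      paste0(" (compound ", paste(compound_id[bad], collapse = ", "), ")")
    } else ""
    stop("`kd` must be positive", who, ": got ",
         paste(kd[bad], collapse = ", "), call. = FALSE)
  }
  constants$gas_constant_R * constants$temperature_T * log(kd * .UM_TO_M)
}

#' Dissociation constant from a binding free energy
#'
#' Exact inverse of [dg_from_kd()]: \eqn{K_D = \exp(\Delta G / RT)}, returned
#' in micromolar.
#'
#' @param dg Binding free energy in kcal/mol. Must be finite.
#' @inheritParams dg_from_kd
#'
#' @return Dissociation constant(s) in micromolar.
#' @examples
#' kd_from_dg(-6.036)  # ~ 38 uM
#' kd_from_dg(0)       # 1e6 uM = 1 M
#' @export
kd_from_dg <- function(dg, constants = thermo_constants()) {
  stopifnot(inherits(constants, "thermo_constants"))
  if (!is.numeric(dg)) stop("`dg` must be numeric (kcal/mol)", call. = FALSE)
  if (any(!is.na(dg) & !is.finite(dg))) {
    stop("`dg` must be finite", call. = FALSE)
  }
  exp(dg / (constants$gas_constant_R * constants$temperature_T)) / .UM_TO_M
}

#' Cross-check printed free energies against their dissociation constants
#'
#' For every row of an affinity table holding both a measured `kd_mean` and a
#' stated `experimental_dg`, recomputes the free energy with [dg_from_kd()]
#' and flags rows where the stated value differs from the recomputed one by
#' more than `tol`.  The default tolerance of 0.0015 kcal/mol covers
#' last-digit rounding of values printed to three decimals.
#'
#' @param table A data frame with columns `compound_id`, `kd_mean` (uM) and
#'   `experimental_dg` (kcal/mol); rows with either value missing are skipped.
#' @param constants A [thermo_constants()] object.
#' @param tol Agreement tolerance in kcal/mol.
#'
#' @return A data frame with one row per checked compound: `compound_id`,
#'   `kd_mean`, `stated_dg`, `recomputed_dg`, `delta`, and logical
#'   `consistent`.
#' @export
validate_affinity_table <- function(table, constants = thermo_constants(),
                                    tol = 0.0015) {
  stopifnot(is.data.frame(table))
  need <- c("compound_id", "kd_mean", "experimental_dg")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  use <- !is.na(table$kd_mean) & !is.na(table$experimental_dg)
  tab <- table[use, , drop = FALSE]
  recomputed <- dg_from_kd(tab$kd_mean, constants, compound_id = tab$compound_id)
  delta <- tab$experimental_dg - recomputed
  data.frame(
    compound_id   = tab$compound_id,
    kd_mean       = tab$kd_mean,
    stated_dg     = tab$experimental_dg,
    recomputed_dg = recomputed,
    delta         = delta,
    consistent    = abs(delta) <= tol,
    stringsAsFactors = FALSE
  )
}
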