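#' Fluorescence-quench titration series
#'
#' Bundles one titration of a fluorescent receptor (e.g. 2 uM tubulin whose
#' intrinsic tryptophan fluorescence is quenched by a bound ligand) with the
#' quantities the dissociation-constant pipeline needs: total ligand
#' concentrations, observed fluorescence, optional excitation/emission
#' absorbances for inner-filter correction, the receptor concentration, and
#' the zero-ligand fluorescence `f0`.
#'
#' `f0` may be supplied explicitly; otherwise exactly one point with
#' `ligand_total == 0` must be present and defines it.  The zero-ligand point
#' is retained in the data but excluded from reciprocal fits downstream.
#'
#' @param ligand_total Total ligand concentrations in uM (>= 0).
#' @param f_observed Observed fluorescence, arbitrary units (> 0).
#' @param a_ex,a_em Optional absorbances at the excitation and emission
#'   wavelengths, one per point (>= 0).
#' @param receptor_total Receptor concentration in uM (> 0), default 2.
#' @param f0 Fluorescence at zero ligand; taken from the zero-ligand point
#'   when `NULL`.
#'
#' @return An object of class `quench_titration`.
#' @export
quench_titration <- function(ligand_total, f_observed, a_ex = NULL,
                             a_em = NULL, receptor_total = 2, f0 = NULL) {
  n <- length(ligand_total)
  if (length(f_observed) != n) {
    stop("`ligand_total` and `f_observed` must have equal length",
         call. = FALSE)
  }
  if (!is.null(a_ex) && length(a_ex) != n) {
    stop("`a_ex` must have one value per point", call. = FALSE)
  }
  if (!is.null(a_em) && length(a_em) != n) {
    stop("`a_em` must have one value per point", call. = FALSE)
  }
  if (any(!is.finite(ligand_total)) || any(ligand_total < 0)) {
    stop("`ligand_total` must be finite and >= 0 (uM)", call. = FALSE)
  }
  if (any(!is.finite(f_observed)) || any(f_observed <= 0)) {
    stop("`f_observed` must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(receptor_total) || length(receptor_total) != 1L ||
      !is.finite(receptor_total) || receptor_total <= 0) {
    stop("`receptor_total` must be a single positive number (uM)",
         call. = FALSE)
  }
  if (is.null(f0)) {
    zero <- which(ligand_total == 0)
    if (length(zero) != 1L) {
      stop("supply `f0` explicitly or include exactly one zero-ligand point",
           call. = FALSE)
    }
    f0 <- f_observed[zero]
  } else if (!is.finite(f0) || f0 <= 0) {
    stop("`f0` must be a positive number", call. = FALSE)
  }
  structure(
    list(ligand_total = as.numeric(ligand_total),
         f_observed = as.numeric(f_observed),
         a_ex = a_ex, a_em = a_em,
         receptor_total = receptor_total, f0 = f0),
    class = "quench_titration"
  )
}

#' @export
print.quench_titration <- function(x, ...) {
  cat("Quench titration:", length(x$ligand_total), "points, ligand",
      min(x$ligand_total), "-", max(x$ligand_total), "uM, receptor",
      x$receptor_total, "uM, f0 =", format(x$f0, digits = 6), "\n")
  if (!is.null(x$a_ex)) cat("  with inner-filter absorbances\n")
  invisible(x)
}

#' @export
as.data.frame.quench_titration <- function(x, ...) {
  out <- data.frame(ligand_total_uM = x$ligand_total,
                    f_observed = x$f_observed)
  if (!is.null(x$a_ex)) out$a_ex <- x$a_ex
  if (!is.null(x$a_em)) out$a_em <- x$a_em
  out
}

#' Inner-filter correction of observed fluorescence
#'
#' Corrects fluorescence for attenuation of the excitation and emission beams
#' by an absorbing ligand:
#' \deqn{F_{corr} = F_{obs} \cdot 10^{(A_{ex} + A_{em})/2}}
#' The correction is multiplicative, never decreases the signal, and grows
#' monotonically with either absorbance.
#'
#' @param f_observed Observed fluorescence (arbitrary units).
#' @param a_ex,a_em Absorbances at the excitation and emission wavelengths
#'   (>= 0); recycled against `f_observed`.
#'
#' @return Corrected fluorescence, same units as `f_observed`.
#' @examples
#' correct_inner_filter(100, 0.1, 0.05)  # 100 * 10^0.075
#' @export
correct_inner_filter <- function(f_observed, a_ex, a_em) {
  if (any(!is.finite(a_ex)) || any(!is.finite(a_em)) ||
      any(a_ex < 0) || any(a_em < 0)) {
    stop("absorbances must be finite and >= 0", call. = FALSE)
  }
  f_observed * 10^((a_ex + a_em) / 2)
}

# corrected fluorescence series for a titration (identity when no absorbances)
.corrected_f <- function(titration) {
  f <- titration$f_observed
  if (!is.null(titration$a_ex) || !is.null(titration$a_em)) {
    a_ex <- if (is.null(titration$a_ex)) 0 else titration$a_ex
    a_em <- if (is.null(titration$a_em)) 0 else titration$a_em
    f <- correct_inner_filter(f, a_ex, a_em)
  }
  f
}

#' Estimate the saturating fluorescence change of a titration
#'
#' Estimates \eqn{\Delta F_{max}}, the fluorescence change at full receptor
#' occupancy, from the double-reciprocal regression of \eqn{1/\Delta F} on
#' \eqn{1/[L]_{total}}: for an ideal single-site binding curve this transform
#' is exactly linear and the fitted intercept equals
#' \eqn{1/\Delta F_{max}}.  The zero-ligand point and any points with
#' \eqn{\Delta F \le 0} are excluded (the latter with a warning).
#'
#' Reciprocal transforms amplify noise at small \eqn{\Delta F}; the fit is
#' unweighted ordinary least squares.
#'
#' @param titration A [quench_titration()] object.
#'
#' @return The estimated \eqn{\Delta F_{max}} in the fluorescence units of
#'   the input.
#' @examples
#' sim <- simulate_quench_titration(quench_sim_config(kd_true = 50, seed = 1))
#' estimate_dfmax(sim)
#' @export
estimate_dfmax <- function(titration) {
  stopifnot(inherits(titration, "quench_titration"))
  f <- .corrected_f(titration)
  df <- titration$f0 - f
  use <- titration$ligand_total > 0
  if (any(use & df <= 0)) {
    warning(sum(use & df <= 0),
            " point(s) with non-positive fluorescence change dropped",
            call. = FALSE)
  }
  use <- use & df > 0
  if (sum(use) < 3L) {
    stop("need at least 3 nonzero-ligand points with positive dF",
         call. = FALSE)
  }
  x <- 1 / titration$ligand_total[use]
  y <- 1 / df[use]
  fit <- stats::lm.fit(cbind(intercept = 1, inv_ligand = x), y)
  b0 <- fit$coefficients[["intercept"]]
  if (!is.finite(b0) || b0 <= 0) {
    stop("unsaturable curve: double-reciprocal intercept is not positive ",
         "(fitted intercept = ", format(b0), ")", call. = FALSE)
  }
  1 / b0
}

#' Estimate a dissociation constant from a quench titration
#'
#' Implements the fractional-occupancy pipeline: fluorescence is
#' inner-filter-corrected when absorbances are present, the occupancy of each
#' point is \eqn{a = \Delta F / \Delta F_{max}}, and the dissociation
#' constant comes from the linearised single-site model
#' \deqn{1/a = K_D/[L]_{free} + 1,}
#' i.e. the slope of the regression of \eqn{1/a} on \eqn{1/[L]_{free}}.
#'
#' Two free-ligand conventions are available.  `"total-as-free"` (default)
#' uses the total ligand concentration, appropriate when the receptor is
#' dilute relative to \eqn{K_D}.  `"iterative-depletion"` refines
#' \eqn{[L]_{free} = [L]_{total} - a \cdot [R]_{total}} and refits until the
#' \eqn{K_D} estimate changes by less than 1e-6 relative (at most 100
#' iterations).
#'
#' With `constrained_intercept = TRUE` the intercept is fixed at 1 (the value
#' the binding model implies) and only the slope is estimated; by default the
#' intercept is free and reported as a model-consistency diagnostic.
#'
#' Points with occupancy above `1 + occupancy_tol` are dropped with a
#' warning; points with \eqn{\Delta F \le 0} are likewise dropped.
#'
#' @param titration A [quench_titration()] object.
#' @param mode `"total-as-free"` or `"iterative-depletion"`.
#' @param constrained_intercept Fix the reciprocal-plot intercept at 1?
#'   Default `FALSE`.
#' @param delta_f_max Saturating fluorescence change; estimated with
#'   [estimate_dfmax()] when `NULL`.
#' @param occupancy_tol Tolerance above 1 before a point is treated as
#'   inconsistent and dropped (default 0.05).
#'
#' @return An object of class `kd_estimate`: a list with `kd` (uM), `slope`
#'   (uM), `intercept`, `r2_fit`, `mode`, `constrained_intercept`,
#'   `delta_f_max`, `iterations`, `n_used`, `dropped` (compound point
#'   indices), and `curve` (a data frame of per-point intermediates:
#'   ligand_free, delta_f, occupancy_a, inv_a, inv_ligand_free).
#' @examples
#' sim <- simulate_quench_titration(quench_sim_config(kd_true = 50, seed = 1))
#' estimate_kd(sim)
#' @export
estimate_kd <- function(titration,
                        mode = c("total-as-free", "iterative-depletion"),
                        constrained_intercept = FALSE,
                        delta_f_max = NULL,
                        occupancy_tol = 0.05) {
  stopifnot(inherits(titration, "quench_titration"))
  mode <- match.arg(mode)
  if (is.null(delta_f_max)) delta_f_max <- estimate_dfmax(titration)
  if (!is.finite(delta_f_max) || delta_f_max <= 0) {
    stop("`delta_f_max` must be positive", call. = FALSE)
  }

  f <- .corrected_f(titration)
  df <- titration$f0 - f
  keep <- titration$ligand_total > 0 & df > 0
  if (any(titration$ligand_total > 0 & df <= 0)) {
    warning(sum(titration$ligand_total > 0 & df <= 0),
            " point(s) with non-positive fluorescence change dropped",
            call. = FALSE)
  }
  a <- df / delta_f_max
  bad_a <- keep & a > 1 + occupancy_tol
  if (any(bad_a)) {
    warning(sum(bad_a), " point(s) with occupancy > 1 dropped (data ",
            "inconsistent with the estimated saturation)", call. = FALSE)
    keep <- keep & !bad_a
  }
  # occupancy marginally above 1 from noise is clipped for the reciprocal
  a_used <- pmin(a[keep], 1)
  L_tot <- titration$ligand_total[keep]
  if (length(a_used) < 2L + !constrained_intercept) {
    stop("too few usable points for the reciprocal fit", call. = FALSE)
  }

  fit_once <- function(L_free) {
    x <- 1 / L_free
    y <- 1 / a_used
    if (constrained_intercept) {
      slope <- sum(x * (y - 1)) / sum(x^2)
      fitted <- slope * x + 1
      intercept <- 1
    } else {
      fit <- stats::lm.fit(cbind(intercept = 1, x = x), y)
      slope <- fit$coefficients[["x"]]
      intercept <- fit$coefficients[["intercept"]]
      fitted <- intercept + slope * x
    }
    ss_res <- sum((y - fitted)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    list(slope = slope, intercept = intercept, r2 = r2)
  }

  iterations <- 0L
  if (mode == "total-as-free") {
    L_free <- L_tot
    res <- fit_once(L_free)
  } else {
    L_free <- L_tot
    res <- fit_once(L_free)
    kd_prev <- res$slope
    trace <- kd_prev
    repeat {
      iterations <- iterations + 1L
      if (iterations > 100L) {
        stop("iterative depletion did not converge in 100 iterations; ",
             "K_D trace: ", paste(signif(trace, 6), collapse = " -> "),
             call. = FALSE)
      }
      a_model <- L_free / (kd_prev + L_free)
      L_free <- pmax(L_tot - a_model * titration$receptor_total,
                     .Machine$double.eps)
      res <- fit_once(L_free)
      trace <- c(trace, res$slope)
      if (abs(res$slope - kd_prev) <= 1e-6 * abs(kd_prev)) break
      kd_prev <- res$slope
    }
  }

  if (!is.finite(res$slope) || res$slope <= 0) {
    stop("reciprocal fit gave a non-positive K_D (slope = ",
         format(res$slope), ")", call. = FALSE)
  }

  structure(
    list(
      kd = res$slope,
      slope = res$slope,
      intercept = res$intercept,
      r2_fit = res$r2,
      mode = mode,
      constrained_intercept = constrained_intercept,
      delta_f_max = delta_f_max,
      iterations = iterations,
      n_used = length(a_used),
      dropped = which((titration$ligand_total > 0 & df <= 0) | bad_a),
      curve = data.frame(
        ligand_free = L_free,
        delta_f = df[keep],
        occupancy_a = a_used,
        inv_a = 1 / a_used,
        inv_ligand_free = 1 / L_free
      )
    ),
    class = "kd_estimate"
  )
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("K_D estimate: %.4g uM  (%s%s)\n", x$kd, x$mode,
              if (x$constrained_intercept) ", intercept fixed at 1" else ""))
  cat(sprintf("  reciprocal fit: slope = %.4g uM, intercept = %.4g, R2 = %.4f\n",
              x$slope, x$intercept, x$r2_fit))
  cat(sprintf("  dF_max = %.4g, %d points used", x$delta_f_max, x$n_used))
  if (length(x$dropped)) cat(",", length(x$dropped), "dropped")
  if (x$mode == "iterative-depletion") cat(",", x$iterations, "iterations")
  cat("\n")
  invisible(x)
}
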