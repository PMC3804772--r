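#' LIE coefficient set
#'
#' Container for the coefficients of the linear interaction energy (LIE)
#' empirical equation
#' \deqn{\Delta G_{bind} = \alpha \langle U_{vdw}\rangle +
#'       \beta \langle U_{elec}\rangle + \gamma \langle U_{cav}\rangle + c}
#' where the three energy terms are ensemble-average bound-minus-free van der
#' Waals, electrostatic and cavity energies (kcal/mol) from a surface
#' generalized Born continuum model, and the intercept `c` defaults to zero.
#' Signs are stored as-is: a fitted equation written with explicit minus signs
#' has negative `beta` and `gamma` here.
#'
#' @param alpha,beta,gamma Dimensionless coefficients multiplying the van der
#'   Waals, electrostatic and cavity terms respectively.
#' @param intercept Constant term in kcal/mol (default 0).
#'
#' @return An object of class `lie_coefficients` (a named numeric vector).
#' @examples
#' lie_coefficients(0.072, -0.006, -0.951)
#' @export
lie_coefficients <- function(alpha, beta, gamma, intercept = 0) {
  co <- c(alpha = alpha, beta = beta, gamma = gamma, intercept = intercept)
  if (!is.numeric(co) || length(co) != 4L || any(!is.finite(co))) {
    stop("all coefficients must be single finite numbers", call. = FALSE)
  }
  structure(co, class = "lie_coefficients")
}

#' @export
print.lie_coefficients <- function(x, digits = 3, ...) {
  cat("LIE coefficients:\n")
  cat(sprintf("  dG = %s*<U_vdw> %+g*<U_elec> %+g*<U_cav>",
              format(round(x[["alpha"]], digits)),
              round(x[["beta"]], digits), round(x[["gamma"]], digits)))
  if (x[["intercept"]] != 0) cat(sprintf(" %+g", round(x[["intercept"]], digits)))
  cat("  (kcal/mol)\n")
  invisible(x)
}

# design matrix for the LIE fit; columns named after the energy terms
.lie_design <- function(table, include_intercept) {
  need <- c("u_vdw", "u_elec", "u_cav")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("missing energy column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(table[, need])
  if (include_intercept) X <- cbind(X, intercept = 1)
  if (any(!is.finite(X))) stop("energy terms must be finite", call. = FALSE)
  X
}

#' Fit the LIE empirical free-energy equation by least squares
#'
#' Ordinary least-squares fit of experimental binding free energies on the
#' three SGB energy components.  The default fit has no intercept, matching
#' the usual form of the fitted equation; `include_intercept = TRUE` adds a
#' constant term for sensitivity analysis.  The solution is computed by QR
#' decomposition; rank deficiency is detected from the singular values of the
#' design matrix at a relative threshold of 1e-10 and reported with the
#' offending columns.
#'
#' @param table Training table: a data frame with columns `compound_id`,
#'   `u_vdw`, `u_elec`, `u_cav` (kcal/mol) and `experimental_dg` (kcal/mol).
#'   Needs at least 4 rows (5 with intercept) and unique compound ids.
#' @param include_intercept Fit a constant term? Default `FALSE`.
#'
#' @return An object of class `lie_fit`: a list with elements
#'   `coefficients` ([lie_coefficients()]), `r2_train` (squared Pearson
#'   correlation of fitted vs experimental), `rmse` (kcal/mol), `residuals`
#'   (named, kcal/mol), `fitted` (named), `n`, and `include_intercept`.
#' @seealso [predict_dg()], [loo_predictions()]
#' @examples
#' tab <- simulate_lie_table(lie_sim_config(n_compounds = 10, seed = 1))
#' fit_lie(tab)
#' @export
fit_lie <- function(table, include_intercept = FALSE) {
  stopifnot(is.data.frame(table))
  if (!"experimental_dg" %in% names(table)) {
    stop("missing column `experimental_dg`", call. = FALSE)
  }
  ids <- if ("compound_id" %in% names(table)) as.character(table$compound_id)
         else as.character(seq_len(nrow(table)))
  if (anyDuplicated(ids)) stop("compound ids must be unique", call. = FALSE)
  p <- 3L + as.integer(include_intercept)
  if (nrow(table) < p + 1L) {
    stop("need at least ", p + 1L, " rows to fit ", p, " coefficients",
         call. = FALSE)
  }
  X <- .lie_design(table, include_intercept)
  y <- table$experimental_dg
  if (any(!is.finite(y))) stop("`experimental_dg` must be finite", call. = FALSE)

  sv <- svd(X, nu = 0, nv = 0)$d
  if (min(sv) < 1e-10 * max(sv)) {
    # identify columns involved in the near-null space for the error message
    v <- svd(X)$v[, which.min(sv)]
    cols <- colnames(X)[abs(v) > 1e-6]
    stop("singular design: collinear column(s) ",
         paste(cols, collapse = ", "), call. = FALSE)
  }

  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  names(fitted) <- names(resid) <- ids

  co <- lie_coefficients(
    alpha = beta[["u_vdw"]], beta = beta[["u_elec"]], gamma = beta[["u_cav"]],
    intercept = if (include_intercept) beta[["intercept"]] else 0
  )
  r2 <- if (stats::var(fitted) > 0) stats::cor(fitted, y)^2 else NA_real_
  structure(
    list(
      coefficients = co,
      r2_train = r2,
      rmse = sqrt(mean(resid^2)),
      residuals = resid,
      fitted = fitted,
      n = nrow(table),
      include_intercept = include_intercept
    ),
    class = "lie_fit"
  )
}

#' @export
print.lie_fit <- function(x, digits = 3, ...) {
  cat("LIE least-squares fit (n =", x$n,
      if (x$include_intercept) "compounds, with intercept)\n"
      else "compounds, no intercept)\n")
  print(x$coefficients, digits = digits)
  cat(sprintf("  R2(train) = %.3f, RMSE = %.3f kcal/mol\n", x$r2_train, x$rmse))
  invisible(x)
}

#' @export
coef.lie_fit <- function(object, ...) object$coefficients

#' Predict binding free energy from energy components
#'
#' Evaluates the LIE equation `alpha*u_vdw + beta*u_elec + gamma*u_cav +
#' intercept` for one or more compounds.
#'
#' @param coeffs A [lie_coefficients()] object (or the `coefficients` of a
#'   [fit_lie()] result).
#' @param energy A data frame with columns `u_vdw`, `u_elec`, `u_cav`
#'   (kcal/mol), or a numeric vector of length 3 in that order.
#'
#' @return Predicted binding free energy in kcal/mol, one value per row.
#' @examples
#' co <- lie_coefficients(0.072, -0.006, -0.951)
#' predict_dg(co, c(-62.62, 76.07, 1.287))  # ~ -6.189
#' @export
predict_dg <- function(coeffs, energy) {
  stopifnot(inherits(coeffs, "lie_coefficients"))
  if (is.numeric(energy) && is.null(dim(energy))) {
    if (length(energy) != 3L) {
      stop("numeric `energy` must have length 3: (u_vdw, u_elec, u_cav)",
           call. = FALSE)
    }
    energy <- data.frame(u_vdw = energy[1], u_elec = energy[2],
                         u_cav = energy[3])
  }
  X <- .lie_design(energy, include_intercept = FALSE)
  out <- drop(X %*% unclass(coeffs)[c("alpha", "beta", "gamma")]) +
    coeffs[["intercept"]]
  if ("compound_id" %in% names(energy)) names(out) <- energy$compound_id
  out
}

#' @export
predict.lie_fit <- function(object, newdata, ...) {
  predict_dg(object$coefficients, newdata)
}

#' Leave-one-out predictions for a LIE training table
#'
#' For each compound, refits the LIE equation on the remaining compounds and
#' predicts the held-out one.  Useful as a diagnostic for how much each row
#' steers the fit, and for comparing printed prediction columns that may have
#' come from a cross-validated scheme.
#'
#' @inheritParams fit_lie
#'
#' @return Named numeric vector of leave-one-out predicted free energies
#'   (kcal/mol), in the table's row order.
#' @export
loo_predictions <- function(table, include_intercept = FALSE) {
  stopifnot(is.data.frame(table))
  p <- 3L + as.integer(include_intercept)
  if (nrow(table) < p + 2L) {
    stop("need at least ", p + 2L, " rows for leave-one-out", call. = FALSE)
  }
  ids <- if ("compound_id" %in% names(table)) as.character(table$compound_id)
         else as.character(seq_len(nrow(table)))
  out <- vapply(seq_len(nrow(table)), function(i) {
    fit <- fit_lie(table[-i, , drop = FALSE], include_intercept)
    unname(predict_dg(fit$coefficients, table[i, , drop = FALSE]))
  }, numeric(1))
  names(out) <- ids
  out
}

#' Squared Pearson correlation of two series
#'
#' The coefficient of determination used when comparing predicted and
#' experimental binding free energies (or docking scores and experiment):
#' the square of the Pearson correlation.  Symmetric in its arguments and
#' invariant to affine rescaling of either series.
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#'
#' @return A single value in \[0, 1\].
#' @examples
#' pearson_r2(1:5, c(2.1, 3.9, 6.2, 8.0, 9.9))
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' One-way ANOVA from group summary statistics
#'
#' Computes the classical between/within mean-square F ratio from per-group
#' means, standard deviations and sizes, without access to the raw data:
#' \eqn{SS_B = \sum n_i(\bar x_i - \bar x)^2},
#' \eqn{SS_W = \sum (n_i - 1) s_i^2},
#' \eqn{F = (SS_B/(k-1)) / (SS_W/(N-k))}.
#'
#' @param means,sds,ns Numeric vectors of per-group means, standard
#'   deviations (>= 0) and sizes (>= 2), all the same length (>= 2 groups).
#'
#' @return A list with `F`, `df1`, `df2`, `p_value`, `ss_between`,
#'   `ss_within`.
#' @examples
#' anova_oneway_from_summary(means = c(0, 1), sds = c(1, 1), ns = c(10, 10))
#' @export
anova_oneway_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L || length(sds) != k || length(ns) != k) {
    stop("need >= 2 groups with matching means, sds and ns", call. = FALSE)
  }
  if (any(ns < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0 && ssb == 0) {
    stop("F undefined: no between- or within-group variation", call. = FALSE)
  }
  df1 <- k - 1L
  df2 <- N - k
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}
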