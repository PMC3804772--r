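# Independent oracles kept deliberately separate from the implementation
# paths they check.

# Brute-force normal-equations solve of the no-intercept (or intercept)
# least-squares problem: beta = (X'X)^{-1} X'y, with X'X inverted explicitly.
oracle_lie_fit <- function(table, include_intercept = FALSE) {
  X <- as.matrix(table[, c("u_vdw", "u_elec", "u_cav")])
  if (include_intercept) X <- cbind(X, intercept = 1)
  y <- table$experimental_dg
  xtx <- t(X) %*% X
  beta <- solve(xtx) %*% (t(X) %*% y)
  resid <- y - drop(X %*% beta)
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(solve(xtx)) * sigma2)
  list(coefficients = drop(beta), se = se, residuals = resid)
}

# Construct a group of raw values with exactly the requested mean and sd
# (n >= 2), for cross-checking the summary-statistic ANOVA against aov().
group_with_moments <- function(mean, sd, n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  x <- x - base::mean(x)
  if (stats::sd(x) > 0) x <- x / stats::sd(x) * sd
  x + mean
}

# Closed-form free ligand under depletion, derived independently from the
# mass balance written as a quadratic in the BOUND concentration.
oracle_free_ligand <- function(L_tot, kd, R_tot) {
  # bound B solves B^2 - (L_tot + R_tot + kd) B + L_tot R_tot = 0, smaller root
  s <- L_tot + R_tot + kd
  B <- (s - sqrt(s^2 - 4 * L_tot * R_tot)) / 2
  L_tot - B
}

# default thermodynamic constants used throughout the reference tables
KCAL_R <- 0.00199
KELVIN_T <- 298
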