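# run code under a temporary RNG state so simulators never disturb the
# caller's random stream
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration for a simulated quench titration
#'
#' Defines the generating conditions of a synthetic fluorescence-quench
#' titration.  Defaults emulate a tubulin tryptophan-quench assay: 2 uM
#' receptor, a ligand series spanning 0-200 uM, and additive Gaussian
#' instrument noise on fluorescence.
#'
#' @param kd_true True dissociation constant in uM (> 0).
#' @param delta_f_max_true True saturating fluorescence change, in (0, f0].
#' @param f0 Zero-ligand fluorescence, arbitrary units.
#' @param receptor_total Receptor concentration in uM.
#' @param ligand_grid Total ligand concentrations in uM (include 0 for the
#'   reference point).
#' @param noise_sd Gaussian noise standard deviation on fluorescence:
#'   absolute units, or a fraction of `f0` when `noise_as_fraction = TRUE`.
#' @param noise_as_fraction Interpret `noise_sd` as a fraction of `f0`?
#' @param binding_model `"ideal"` (free ligand = total) or `"depletion"`
#'   (free ligand solves the single-site mass balance exactly).
#' @param extinction_ex,extinction_em Optional extinction factors
#'   (absorbance per uM ligand); when positive, linear absorbance columns
#'   are emitted for inner-filter correction.
#' @param seed Integer seed; the generator is local to each simulation call.
#'
#' @return An object of class `quench_sim_config`.
#' @export
quench_sim_config <- function(kd_true, delta_f_max_true = 400, f0 = 1000,
                              receptor_total = 2,
                              ligand_grid = c(0, 10, 25, 50, 100, 150, 200),
                              noise_sd = 0, noise_as_fraction = FALSE,
                              binding_model = c("ideal", "depletion"),
                              extinction_ex = 0, extinction_em = 0,
                              seed = 1L) {
  binding_model <- match.arg(binding_model)
  if (!is.finite(kd_true) || kd_true <= 0) {
    stop("`kd_true` must be positive (uM)", call. = FALSE)
  }
  if (!is.finite(f0) || f0 <= 0) stop("`f0` must be positive", call. = FALSE)
  if (!is.finite(delta_f_max_true) || delta_f_max_true <= 0 ||
      delta_f_max_true > f0) {
    stop("`delta_f_max_true` must lie in (0, f0]", call. = FALSE)
  }
  if (!is.finite(receptor_total) || receptor_total <= 0) {
    stop("`receptor_total` must be positive (uM)", call. = FALSE)
  }
  if (any(!is.finite(ligand_grid)) || any(ligand_grid < 0)) {
    stop("`ligand_grid` must be finite and >= 0 (uM)", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (extinction_ex < 0 || extinction_em < 0) {
    stop("extinction factors must be >= 0", call. = FALSE)
  }
  structure(
    list(kd_true = kd_true, delta_f_max_true = delta_f_max_true, f0 = f0,
         receptor_total = receptor_total, ligand_grid = ligand_grid,
         noise_sd = noise_sd, noise_as_fraction = noise_as_fraction,
         binding_model = binding_model,
         extinction_ex = extinction_ex, extinction_em = extinction_em,
         seed = seed),
    class = "quench_sim_config"
  )
}

#' Free-ligand concentration under single-site receptor depletion
#'
#' Solves the mass balance
#' \eqn{[L]_{total} = [L]_{free} + a \cdot [R]_{total}} with
#' \eqn{a = [L]_{free}/(K_D + [L]_{free})} exactly: the positive root of
#' \deqn{L_f^2 + (K_D + R - L_t) L_f - K_D L_t = 0.}
#'
#' @param ligand_total Total ligand in uM (vectorised).
#' @param kd Dissociation constant in uM.
#' @param receptor_total Receptor concentration in uM.
#'
#' @return Free-ligand concentration(s) in uM.
#' @export
free_ligand_depletion <- function(ligand_total, kd, receptor_total) {
  b <- kd + receptor_total - ligand_total
  # numerically stable positive root of the binding quadratic
  (-b + sqrt(b^2 + 4 * kd * ligand_total)) / 2
}

#' Simulate a fluorescence-quench titration
#'
#' Forward model of the single-site quench assay.  Occupancy at each ligand
#' concentration is \eqn{a = L/(K_D + L)} with \eqn{L} the total ligand
#' (`"ideal"`) or the exact mass-balance free ligand (`"depletion"`); the
#' noiseless fluorescence is \eqn{F = f_0 - a\,\Delta F_{max}}, to which
#' Gaussian noise is added.  Reproducible given the config seed, without
#' touching the caller's RNG state.
#'
#' @param config A [quench_sim_config()] object.
#'
#' @return A [quench_titration()] object; the true free-ligand and occupancy
#'   series are attached as attributes `"truth"` for oracle use in tests.
#' @examples
#' simulate_quench_titration(quench_sim_config(kd_true = 38, seed = 7))
#' @export
simulate_quench_titration <- function(config) {
  stopifnot(inherits(config, "quench_sim_config"))
  L_tot <- config$ligand_grid
  L_free <- switch(config$binding_model,
    ideal = L_tot,
    depletion = free_ligand_depletion(L_tot, config$kd_true,
                                      config$receptor_total)
  )
  a <- L_free / (config$kd_true + L_free)
  f_clean <- config$f0 - a * config$delta_f_max_true
  sd_abs <- if (config$noise_as_fraction) config$noise_sd * config$f0
            else config$noise_sd
  f <- if (sd_abs > 0) {
    eps <- .with_seed(config$seed, stats::rnorm(length(f_clean), 0, sd_abs))
    # the zero-ligand reference is averaged heavily in practice; keep it exact
    eps[L_tot == 0] <- 0
    f_clean + eps
  } else f_clean
  f <- pmax(f, .Machine$double.eps)

  a_ex <- if (config$extinction_ex > 0) config$extinction_ex * L_tot else NULL
  a_em <- if (config$extinction_em > 0) config$extinction_em * L_tot else NULL
  out <- quench_titration(L_tot, f, a_ex = a_ex, a_em = a_em,
                          receptor_total = config$receptor_total,
                          f0 = config$f0)
  attr(out, "truth") <- list(ligand_free = L_free, occupancy = a,
                             f_clean = f_clean)
  out
}

#' Configuration for a simulated LIE training table
#'
#' Generating conditions for synthetic LIE training data: energy components
#' drawn uniformly from realistic SGB ranges and free energies from a known
#' coefficient triple plus Gaussian noise.  The default ranges span the
#' values observed for noscapinoid-tubulin complexes
#' (u_vdw in \[-66, -46\], u_elec in \[7, 130\], u_cav in \[0.4, 2.1\]
#' kcal/mol).
#'
#' @param coeffs_true A [lie_coefficients()] object generating the table.
#' @param n_compounds Number of rows (>= 4).
#' @param u_vdw_range,u_elec_range,u_cav_range Uniform sampling intervals in
#'   kcal/mol.
#' @param noise_sd Gaussian noise standard deviation on the free energy in
#'   kcal/mol (>= 0).
#' @param seed Integer seed.
#'
#' @return An object of class `lie_sim_config`.
#' @export
lie_sim_config <- function(coeffs_true = lie_coefficients(0.072, -0.006, -0.951),
                           n_compounds = 10,
                           u_vdw_range = c(-66, -46),
                           u_elec_range = c(7, 130),
                           u_cav_range = c(0.4, 2.1),
                           noise_sd = 0, seed = 1L) {
  stopifnot(inherits(coeffs_true, "lie_coefficients"))
  if (n_compounds < 4) stop("`n_compounds` must be >= 4", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  for (rng in list(u_vdw_range, u_elec_range, u_cav_range)) {
    if (length(rng) != 2L || any(!is.finite(rng)) || rng[1] >= rng[2]) {
      stop("energy ranges must be finite increasing length-2 intervals",
           call. = FALSE)
    }
  }
  structure(
    list(coeffs_true = coeffs_true, n_compounds = as.integer(n_compounds),
         u_vdw_range = u_vdw_range, u_elec_range = u_elec_range,
         u_cav_range = u_cav_range, noise_sd = noise_sd, seed = seed),
    class = "lie_sim_config"
  )
}

#' Simulate a LIE training table
#'
#' Draws energy components uniformly from the configured ranges and computes
#' `experimental_dg` from the true coefficients plus Gaussian noise.
#'
#' @param config A [lie_sim_config()] object.
#'
#' @return A data frame with columns `compound_id`, `u_vdw`, `u_elec`,
#'   `u_cav`, `experimental_dg`, suitable for [fit_lie()].
#' @examples
#' simulate_lie_table(lie_sim_config(n_compounds = 6, seed = 3))
#' @export
simulate_lie_table <- function(config) {
  stopifnot(inherits(config, "lie_sim_config"))
  n <- config$n_compounds
  .with_seed(config$seed, {
    tab <- data.frame(
      compound_id = sprintf("sim%02d", seq_len(n)),
      u_vdw  = stats::runif(n, config$u_vdw_range[1],  config$u_vdw_range[2]),
      u_elec = stats::runif(n, config$u_elec_range[1], config$u_elec_range[2]),
      u_cav  = stats::runif(n, config$u_cav_range[1],  config$u_cav_range[2]),
      stringsAsFactors = FALSE
    )
    tab$experimental_dg <- predict_dg(config$coeffs_true, tab) +
      if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
    tab
  })
}
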