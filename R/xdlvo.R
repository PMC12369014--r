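#' Physicochemical parameters of the bacterium--substrate interaction
#'
#' Parameters of the extended-DLVO (xDLVO) description of a spherical
#' bacterium near a flat substrate: Lifshitz--van der Waals attraction set
#' by the Hamaker constant, constant-potential electrostatic double-layer
#' interaction set by the surface potentials and Debye length, and a
#' short-range Lewis acid--base term decaying exponentially from the
#' contact separation.
#'
#' Defaults are literature-typical for a Gram-positive coccus in
#' physiological ionic strength: Hamaker constant 1e-20 J, cell radius
#' 0.4 um, surface potentials -15 mV (cell) and -20 mV (substrate), Debye
#' length ~0.77 nm (kappa = 1.3e9 1/m), water permittivity 78.5, acid-base
#' contact energy -3 mJ/m^2, decay length 0.6 nm, and the conventional
#' contact minimum h0 = 0.157 nm.
#'
#' @param A_H Hamaker constant, J.
#' @param R_b Bacterium radius, m.
#' @param psi_b,psi_s Bacterium and substrate surface potentials, V.
#' @param kappa Inverse Debye length, 1/m.
#' @param eps_r Relative permittivity of the medium.
#' @param eps_0 Vacuum permittivity, F/m.
#' @param dG_AB_h0 Acid--base interaction energy per unit area at contact
#'   separation, J/m^2 (negative = hydrophobic attraction).
#' @param lambda_AB Acid--base decay length, m.
#' @param h0 Minimum (contact) separation, m.
#' @return An object of class `xdlvo_params`.
#' @export
xdlvo_params <- function(A_H = 1e-20, R_b = 0.4e-6,
                         psi_b = -15e-3, psi_s = -20e-3,
                         kappa = 1.3e9, eps_r = 78.5,
                         eps_0 = 8.8541878128e-12,
                         dG_AB_h0 = -3e-3, lambda_AB = 0.6e-9,
                         h0 = 0.157e-9) {
  if (R_b <= 0 || kappa <= 0 || lambda_AB <= 0 || h0 <= 0 || eps_r <= 0)
    stop("R_b, kappa, lambda_AB, h0 and eps_r must all be positive")
  structure(list(A_H = A_H, R_b = R_b, psi_b = psi_b, psi_s = psi_s,
                 kappa = kappa, eps_r = eps_r, eps_0 = eps_0,
                 dG_AB_h0 = dG_AB_h0, lambda_AB = lambda_AB, h0 = h0),
            class = "xdlvo_params")
}

#' xDLVO interaction energy profile (sphere--plate)
#'
#' Evaluates the three xDLVO components and their sum at each separation:
#' \itemize{
#'   \item Lifshitz--van der Waals: `U_LW(h) = -A_H R_b / (6 h)`
#'   \item electrostatic double layer (constant potential):
#'     `U_EL(h) = pi eps_r eps_0 R_b [ 2 psi_b psi_s
#'       ln((1 + e^{-kappa h}) / (1 - e^{-kappa h}))
#'       + (psi_b^2 + psi_s^2) ln(1 - e^{-2 kappa h}) ]`
#'   \item Lewis acid--base:
#'     `U_AB(h) = 2 pi R_b lambda_AB dG_AB_h0 e^{(h0 - h)/lambda_AB}`
#' }
#'
#' @param p An [xdlvo_params()] object.
#' @param h_grid Separations, m; all must be positive.
#' @return A data.frame with columns `h`, `U_LW`, `U_EL`, `U_AB`,
#'   `U_total`, energies in J.
#' @examples
#' p <- xdlvo_params()
#' prof <- energy_profile(p, seq(0.2e-9, 50e-9, length.out = 200))
#' @export
energy_profile <- function(p, h_grid) {
  stopifnot(inherits(p, "xdlvo_params"), is.numeric(h_grid))
  if (any(h_grid <= 0)) stop("all separations must be positive")
  h <- as.numeric(h_grid)
  U_LW <- -p$A_H * p$R_b / (6 * h)
  ekh <- exp(-p$kappa * h)
  if (any(1 - ekh <= 0) || any(1 - ekh^2 <= 0))
    stop("separation too small for the double-layer expression (kappa*h ~ 0)")
  U_EL <- pi * p$eps_r * p$eps_0 * p$R_b *
    (2 * p$psi_b * p$psi_s * log((1 + ekh) / (1 - ekh)) +
       (p$psi_b^2 + p$psi_s^2) * log(1 - ekh^2))
  U_AB <- 2 * pi * p$R_b * p$lambda_AB * p$dG_AB_h0 *
    exp((p$h0 - h) / p$lambda_AB)
  data.frame(h = h, U_LW = U_LW, U_EL = U_EL, U_AB = U_AB,
             U_total = U_LW + U_EL + U_AB)
}

#' Locate the deepest attractive minimum of an interaction profile
#'
#' Scans `U_total` on a dense grid over `h_range` and refines the deepest
#' strict local minimum with [stats::optimize()]. Profiles that are
#' monotone over the range (e.g. purely attractive) have no minimum.
#'
#' @param p An [xdlvo_params()] object.
#' @param h_range Length-2 positive separations, m.
#' @param n_grid Scan resolution.
#' @return A list `(h_min, U_min)` in m and J, or `NULL` if the profile has
#'   no interior local minimum in the range.
#' @export
secondary_minimum <- function(p, h_range, n_grid = 4096L) {
  stopifnot(length(h_range) == 2L, all(h_range > 0), h_range[1] < h_range[2])
  h <- seq(h_range[1], h_range[2], length.out = n_grid)
  U <- energy_profile(p, h)$U_total
  interior <- which(diff(sign(diff(U))) > 0) + 1L  # strict local minima
  if (length(interior) == 0L) return(NULL)
  i <- interior[which.min(U[interior])]
  lo <- h[max(1L, i - 1L)]; hi <- h[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(x) energy_profile(p, x)$U_total,
                         interval = c(lo, hi))
  list(h_min = opt$minimum, U_min = opt$objective)
}

#' Gaussian sampler of per-contact interaction energies
#'
#' The simulator treats the total xDLVO energy of each contact event as a
#' Gaussian random variable shared across substrates; substrate identity
#' enters only through the adhesion threshold the draw is compared with.
#'
#' @param mu Location, J.
#' @param sigma Spread, J; must be positive.
#' @return An object of class `energy_sampler`.
#' @export
energy_sampler <- function(mu, sigma) {
  stopifnot(is.numeric(mu), is.numeric(sigma), length(mu) == 1L,
            length(sigma) == 1L, is.finite(mu), is.finite(sigma))
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(mu = mu, sigma = sigma), class = "energy_sampler")
}

#' @export
print.energy_sampler <- function(x, ...) {
  cat(sprintf("Gaussian energy sampler: mu = %.4g J, sigma = %.4g J\n",
              x$mu, x$sigma))
  invisible(x)
}

#' Calibrate the shared energy sampler to two threshold exceedance
#' probabilities
#'
#' Solves for the Gaussian `(mu, sigma)` such that a draw falls below the
#' hydro-softened threshold with probability `p_soft` and below the
#' unsoftened threshold with probability `p_unsoft`:
#' `Phi((threshold - mu)/sigma) = p` for each substrate, `Phi` the standard
#' normal CDF. Two thresholds and two probabilities determine `(mu, sigma)`
#' exactly via normal quantiles.
#'
#' @param threshold_soft,threshold_unsoft Adhesion thresholds, J;
#'   `threshold_soft` must be less negative than `threshold_unsoft`.
#' @param p_soft,p_unsoft Target per-contact adhesion probabilities,
#'   `0 < p_unsoft < p_soft < 1`.
#' @return An [energy_sampler()].
#' @examples
#' calibrate_sampler(-1.2e-12, -1.6e-12, 0.1782, 0.0321)
#' @export
calibrate_sampler <- function(threshold_soft, threshold_unsoft,
                              p_soft, p_unsoft) {
  if (!(threshold_soft > threshold_unsoft))
    stop("threshold_soft must exceed (be less negative than) threshold_unsoft")
  if (!(p_unsoft > 0 && p_soft < 1 && p_unsoft < p_soft))
    stop("require 0 < p_unsoft < p_soft < 1")
  z_s <- stats::qnorm(p_soft)
  z_u <- stats::qnorm(p_unsoft)
  sigma <- (threshold_soft - threshold_unsoft) / (z_s - z_u)
  if (!is.finite(sigma) || sigma <= 0)
    stop("calibration error: no positive-sigma solution")
  mu <- threshold_soft - sigma * z_s
  energy_sampler(mu, sigma)
}

#' Default calibrated sampler
#'
#' Runs the calibration chain that fixes the shipped sampler: the two
#' default substrate thresholds together with per-contact adhesion
#' probabilities chosen so that the expected 24 h ensemble means under the
#' default growth schedule equal the study's simulated means (about 1000
#' and 180 adhered bacteria). Yields mu ~ -0.803e-12 J,
#' sigma ~ 0.431e-12 J.
#'
#' @return An [energy_sampler()].
#' @export
default_sampler <- function() {
  n_att <- sum(round(logistic_population(growth_params(), c(6, 12, 18, 24))))
  calibrate_sampler(adhesion_threshold_energy(hydro_softened_substrate()),
                    adhesion_threshold_energy(unsoftened_substrate()),
                    p_soft = 1000 / n_att, p_unsoft = 180 / n_att)
}

#' Draw interaction energies from a sampler
#'
#' @param s An [energy_sampler()].
#' @param n Number of i.i.d. draws (>= 1).
#' @param seed Optional integer seed for reproducible draws; `NULL` uses
#'   the current RNG state.
#' @return Numeric vector of energies, J.
#' @export
sample_energy <- function(s, n, seed = NULL) {
  stopifnot(inherits(s, "energy_sampler"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mean = s$mu, sd = s$sigma)
}

#' Convert an energy in joules to units of kT
#'
#' Display helper; the model itself works in joules.
#'
#' @param U Energy, J.
#' @param temperature Kelvin.
#' @return Energy in thermal units kT.
#' @export
joules_to_kT <- function(U, temperature = 298.15) {
  U / (1.380649e-23 * temperature)
}

#' Export an energy profile to CSV
#'
#' @param profile Data frame from [energy_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
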