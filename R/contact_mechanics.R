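#' Substrate mechanical description
#'
#' Bundles the three quantities that determine the adhesion threshold of a
#' film condition: the effective elastic modulus of the bacterium--substrate
#' contact, the interfacial energy (effective work of adhesion) released per
#' unit contact area, and the effective contact radius of the adhering cell.
#'
#' @param E_star Effective elastic modulus, Pa. Must be positive.
#' @param delta_gamma Interfacial energy (work of adhesion), J/m^2.
#'   Must be non-negative.
#' @param R Effective contact radius, m. Must be positive.
#' @param label Free-text label for the condition.
#'
#' @return An object of class `substrate_mechanics`: a list with fields
#'   `E_star`, `delta_gamma`, `R`, `label`.
#'
#' @examples
#' substrate_mechanics(1.8e6, 1.5, 0.104e-6, "hydro-softened")
#' @export
substrate_mechanics <- function(E_star, delta_gamma, R, label = "") {
  stopifnot(is.numeric(E_star), length(E_star) == 1L, is.finite(E_star),
            is.numeric(delta_gamma), length(delta_gamma) == 1L,
            is.finite(delta_gamma),
            is.numeric(R), length(R) == 1L, is.finite(R))
  if (E_star <= 0) stop("E_star must be positive (Pa)")
  if (R <= 0) stop("R must be positive (m)")
  if (delta_gamma < 0) stop("delta_gamma must be non-negative (J/m^2)")
  structure(list(E_star = E_star, delta_gamma = delta_gamma, R = R,
                 label = as.character(label)),
            class = "substrate_mechanics")
}

#' @export
print.substrate_mechanics <- function(x, ...) {
  cat(sprintf("Substrate%s: E* = %.4g MPa, delta_gamma = %.4g J/m^2, R = %.4g um\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$E_star / 1e6, x$delta_gamma, x$R * 1e6))
  invisible(x)
}

#' Default film conditions
#'
#' Parameter sets for the hydro-softened and unsoftened chitosan films:
#' moduli 1.8 and 85 MPa, interfacial energies 1.5 and 6.4 J/m^2, and
#' effective contact radii 0.104 and 0.145 um chosen so the Griffith
#' threshold energies evaluate to -1.2e-12 J and -1.6e-12 J respectively.
#'
#' @return A `substrate_mechanics` object.
#' @rdname default_substrates
#' @export
hydro_softened_substrate <- function() {
  substrate_mechanics(1.8e6, 1.5, 0.104e-6, "hydro-softened")
}

#' @rdname default_substrates
#' @export
unsoftened_substrate <- function() {
  substrate_mechanics(85e6, 6.4, 0.145e-6, "unsoftened")
}

#' Critical contact radius of the JKR--Griffith threshold
#'
#' The Griffith energy balance applied to a JKR adhesive contact gives the
#' critical contact radius above which attachment is stable:
#' `a_critical = (9 * pi * delta_gamma * R^2 / (2 * E_star))^(1/3)`.
#' It grows with the work of adhesion and contact radius and shrinks with
#' stiffness, so soft, low-energy films admit stable contacts at smaller
#' contact zones.
#'
#' @param sub A [substrate_mechanics()] object.
#' @return Critical contact radius, m.
#' @examples
#' critical_contact_radius(hydro_softened_substrate())  # ~5.03e-7 m
#' @export
critical_contact_radius <- function(sub) {
  stopifnot(inherits(sub, "substrate_mechanics"))
  (9 * pi * sub$delta_gamma * sub$R^2 / (2 * sub$E_star))^(1 / 3)
}

#' Adhesion threshold energy of a substrate
#'
#' Interfacial energy released over the critical contact disc:
#' `U_threshold = -pi * a_critical^2 * delta_gamma`. Negative by
#' convention; a less negative value means a lower barrier to stable
#' attachment. Scales as `E_star^(-2/3)` and `delta_gamma^(5/3)`.
#'
#' @inheritParams critical_contact_radius
#' @return Threshold energy, J (<= 0).
#' @examples
#' adhesion_threshold_energy(hydro_softened_substrate())  # ~ -1.2e-12 J
#' adhesion_threshold_energy(unsoftened_substrate())      # ~ -1.6e-12 J
#' @export
adhesion_threshold_energy <- function(sub) {
  a <- critical_contact_radius(sub)
  -pi * a^2 * sub$delta_gamma
}

#' Fit the power-law exponent of the threshold energy along a parameter sweep
#'
#' Given substrates that vary exactly one of `E_star` or `delta_gamma`
#' (all other fields fixed), fits the least-squares slope of
#' `log|U_threshold|` against the log of the varying parameter. The
#' threshold model implies slopes of exactly -2/3 for a modulus sweep and
#' 5/3 for an interfacial-energy sweep.
#'
#' @param sub_grid List of [substrate_mechanics()] objects (>= 3) varying
#'   one parameter over at least one decade.
#' @return Fitted exponent (dimensionless).
#' @examples
#' subs <- lapply(c(1e6, 1e7, 1e8), substrate_mechanics,
#'                delta_gamma = 1.5, R = 1e-7)
#' fit_scaling_exponents(subs)  # -0.6667
#' @export
fit_scaling_exponents <- function(sub_grid) {
  stopifnot(is.list(sub_grid),
            all(vapply(sub_grid, inherits, logical(1), "substrate_mechanics")))
  if (length(sub_grid) < 3L)
    stop("need at least 3 substrates to fit a scaling exponent")
  E <- vapply(sub_grid, `[[`, numeric(1), "E_star")
  g <- vapply(sub_grid, `[[`, numeric(1), "delta_gamma")
  R <- vapply(sub_grid, `[[`, numeric(1), "R")
  if (length(unique(R)) != 1L)
    stop("R must be fixed across the sweep")
  vary_E <- length(unique(E)) > 1L
  vary_g <- length(unique(g)) > 1L
  if (vary_E && vary_g)
    stop("sweep must vary exactly one of E_star or delta_gamma")
  if (!vary_E && !vary_g)
    stop("degenerate sweep: varying parameter is constant")
  x <- log(if (vary_E) E else g)
  U <- vapply(sub_grid, adhesion_threshold_energy, numeric(1))
  if (any(U == 0)) stop("zero threshold energy in sweep (delta_gamma = 0?)")
  y <- log(abs(U))
  unname(stats::coef(stats::lm.fit(cbind(1, x), y))[2L])
}

#' Threshold-energy landscape over modulus and interfacial energy
#'
#' Evaluates `log10|U_threshold|` on an `n x n` grid of logarithmically
#' spaced elastic moduli and interfacial energies at fixed contact radius,
#' the contour landscape used to position film conditions by their
#' adhesion propensity (light/low-|U| regions adhere more readily).
#'
#' @param E_range Length-2 positive numeric, Pa, modulus axis limits.
#' @param gamma_range Length-2 positive numeric, J/m^2, interfacial-energy
#'   axis limits.
#' @param n Grid size per axis (>= 2).
#' @param R Effective contact radius, m.
#' @return A list of class `threshold_landscape` with `E_star` (length n),
#'   `delta_gamma` (length n), and `log10_absU` (n x n matrix, rows index
#'   `E_star`, columns `delta_gamma`).
#' @export
threshold_landscape <- function(E_range, gamma_range, n = 100L, R = 0.104e-6) {
  stopifnot(length(E_range) == 2L, length(gamma_range) == 2L, n >= 2L)
  if (any(E_range <= 0) || any(gamma_range <= 0))
    stop("range bounds must be positive")
  Ev <- exp(seq(log(E_range[1]), log(E_range[2]), length.out = n))
  gv <- exp(seq(log(gamma_range[1]), log(gamma_range[2]), length.out = n))
  # |U| = pi * gamma * (9 pi gamma R^2 / (2 E))^(2/3): vectorised outer product
  absU <- outer(Ev, gv, function(E, g) pi * g * (9 * pi * g * R^2 / (2 * E))^(2 / 3))
  structure(list(E_star = Ev, delta_gamma = gv, log10_absU = log10(absU), R = R),
            class = "threshold_landscape")
}

#' @export
print.threshold_landscape <- function(x, ...) {
  cat(sprintf(
    "Threshold landscape: %d x %d log-spaced grid, E* in [%.3g, %.3g] Pa, delta_gamma in [%.3g, %.3g] J/m^2\n",
    length(x$E_star), length(x$delta_gamma),
    min(x$E_star), max(x$E_star), min(x$delta_gamma), max(x$delta_gamma)))
  invisible(x)
}

#' Plot a threshold landscape as filled contours
#'
#' @param x A `threshold_landscape`.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.threshold_landscape <- function(x, ...) {
  graphics::filled.contour(log10(x$E_star), log10(x$delta_gamma), x$log10_absU,
                           xlab = "log10 E* (Pa)",
                           ylab = "log10 delta_gamma (J/m^2)",
                           main = "log10 |U_threshold| (J)", ...)
}

#' Export a threshold landscape to CSV
#'
#' Writes a long-format table (E_star, delta_gamma, log10_absU).
#'
#' @param x A `threshold_landscape`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(x, path) {
  stopifnot(inherits(x, "threshold_landscape"))
  df <- expand.grid(E_star = x$E_star, delta_gamma = x$delta_gamma,
                    KEEP.OUT.ATTRS = FALSE)
  df$log10_absU <- as.vector(x$log10_absU)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
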