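#' Parameters of the disulfide energy function
#'
#' The energy assigned to a candidate bridge is a sum of non-negative
#' strain terms: a chi3 torsional term with minima at the two angles where
#' native disulfide torsions cluster (-87 and about +97 degrees with the
#' defaults), a threefold chi1 rotamer term for each cysteine, and a
#' harmonic term on each CB-SG-SG' bond angle. The chi3 term is
#'
#'   E(chi3) = a3 * (1 - cos(k3 * (chi3 + phi3)))
#'
#' with the cosine argument in degrees. The energy is a relative
#' geometry-conformity score for comparing candidate bridges within a
#' structure, not a free-energy estimate.
#'
#' @param a3 Amplitude of the chi3 term, kcal/mol.
#' @param k3 Periodicity factor of the chi3 term (dimensionless).
#' @param phi3 Offset of the chi3 term, degrees.
#' @param a1 Amplitude of the chi1 rotamer term, kcal/mol.
#' @param k_theta Harmonic force constant on the CB-SG-SG' angles,
#'   kcal/mol/deg^2.
#' @param theta0 Ideal CB-SG-SG' angle, degrees.
#'
#' @return An object of class `energy_params` (a named list).
#' @export
#' @examples
#' energy_params()
energy_params <- function(a3 = 4.0, k3 = 1.957, phi3 = 87,
                          a1 = 1.4, k_theta = 0.015, theta0 = 104.9) {
  p <- list(a3 = a3, k3 = k3, phi3 = phi3, a1 = a1,
            k_theta = k_theta, theta0 = theta0)
  if (any(!vapply(p, function(z) is.numeric(z) && length(z) == 1L && is.finite(z),
                  logical(1L))))
    stop("energy_params: all parameters must be single finite numbers")
  if (p$a3 < 0 || p$a1 < 0 || p$k_theta < 0)
    stop("energy_params: amplitudes a3, a1 and k_theta must be >= 0")
  structure(p, class = "energy_params")
}

#' Chi3 torsional energy term
#'
#' `a3 * (1 - cos(k3 * (chi3 + phi3)))`, argument in degrees. With default
#' parameters the minima within (-180, 180] fall at -87 and +96.96 degrees
#' (+97 to the nearest degree) and the maximum value is `2 * a3` = 8
#' kcal/mol.
#'
#' @param chi3 Disulfide torsion CB-SG-SG'-CB', degrees. Vectorized.
#' @param params An [energy_params()] object.
#' @return Energy in kcal/mol (>= 0).
#' @export
#' @examples
#' e_chi3(-87) # 0
#' e_chi3(97)  # ~5e-6
e_chi3 <- function(chi3, params = energy_params()) {
  stopifnot(is.numeric(chi3), all(is.finite(chi3)))
  params$a3 * (1 - cos(deg2rad(params$k3 * (chi3 + params$phi3))))
}

#' Chi1 rotamer energy term
#'
#' Threefold cosine potential `a1 * (1 + cos(3 * chi1))` with zeros at the
#' canonical side-chain rotamers chi1 = -60, +60 and 180 degrees.
#'
#' @param chi1 Side-chain torsion N-CA-CB-SG, degrees. Vectorized.
#' @inheritParams e_chi3
#' @return Energy in kcal/mol (>= 0).
#' @export
e_chi1 <- function(chi1, params = energy_params()) {
  stopifnot(is.numeric(chi1), all(is.finite(chi1)))
  params$a1 * (1 + cos(deg2rad(3 * chi1)))
}

#' Harmonic bond-angle strain term
#'
#' `k_theta * (theta - theta0)^2`, zero at the ideal CB-SG-SG' angle.
#'
#' @param theta CB-SG-SG' bond angle, degrees. Vectorized.
#' @inheritParams e_chi3
#' @return Energy in kcal/mol (>= 0).
#' @export
e_angle <- function(theta, params = energy_params()) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  params$k_theta * (theta - params$theta0)^2
}

#' Total energy of a modeled disulfide bridge
#'
#' Sum of the chi1 terms of both cysteines, the chi3 torsional term, and
#' the harmonic strain on both CB-SG-SG' angles. All arguments are
#' vectorized together.
#'
#' @param chi1_a,chi1_b Chi1 torsions of the two residues, degrees.
#' @param chi3 Disulfide torsion, degrees.
#' @param theta_a,theta_b CB-SG-SG' angles at the two sulfurs, degrees.
#' @inheritParams e_chi3
#' @param breakdown If `TRUE`, return a data frame with the individual
#'   terms alongside the total.
#' @return Total energy in kcal/mol, or a data frame when
#'   `breakdown = TRUE`.
#' @export
#' @examples
#' total_energy(-60, 180, -87, 104.9, 104.9) # 0
total_energy <- function(chi1_a, chi1_b, chi3, theta_a, theta_b,
                         params = energy_params(), breakdown = FALSE) {
  ea <- e_chi1(chi1_a, params)
  eb <- e_chi1(chi1_b, params)
  e3 <- e_chi3(chi3, params)
  eta <- e_angle(theta_a, params)
  etb <- e_angle(theta_b, params)
  tot <- ea + eb + e3 + eta + etb
  if (!breakdown) return(tot)
  data.frame(e_chi1_a = ea, e_chi1_b = eb, e_chi3 = e3,
             e_angle_a = eta, e_angle_b = etb, energy = tot)
}

#' Locate the chi3 energy minima by fine-grid search
#'
#' Evaluates the chi3 term on a regular grid over an interval and returns
#' the minimizing angle. Used to verify that the implemented term has its
#' minima at the torsion values observed in native disulfides.
#'
#' @param lower,upper Interval bounds, degrees.
#' @param step Grid spacing, degrees.
#' @inheritParams e_chi3
#' @param include_upper Whether the upper bound is part of the grid.
#' @return The grid angle (degrees) with the smallest chi3 energy.
#' @export
#' @examples
#' chi3_minimum(-180, 0, include_upper = FALSE) # -87
#' chi3_minimum(0, 180)                         # 96.96
chi3_minimum <- function(lower, upper, step = 0.01,
                         params = energy_params(), include_upper = TRUE) {
  grid <- seq(lower, upper, by = step)
  if (!include_upper && grid[length(grid)] >= upper)
    grid <- grid[grid < upper]
  grid[which.min(e_chi3(grid, params))]
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Disulfide energy function parameters:\n")
  cat(sprintf("  chi3 term : %.3g * (1 - cos(%.4g * (chi3 + %.4g)))\n",
              x$a3, x$k3, x$phi3))
  cat(sprintf("  chi1 term : %.3g * (1 + cos(3 * chi1))\n", x$a1))
  cat(sprintf("  angle term: %.3g * (theta - %.4g)^2\n", x$k_theta, x$theta0))
  invisible(x)
}
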