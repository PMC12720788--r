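#' Equilibrium 1:1 complex concentration and fractional occupancy
#'
#' Solves the quadratic mass-balance for a 1:1 protein-ligand complex,
#' `PI = ((P0 + I0 + KD) - sqrt((P0 + I0 + KD)^2 - 4 P0 I0)) / 2`,
#' using the subtraction-safe equivalent `PI = 2 P0 I0 / (P0 + I0 + KD + sqrt(...))`
#' (the naive root loses precision when `4 P0 I0` is small relative to
#' `(P0 + I0 + KD)^2`). Fractional occupancy is `theta = PI / P0`.
#'
#' Concentrations are unit-agnostic but must share one unit.
#'
#' @param kd Dissociation constant.
#' @param p0 Total protein concentration (> 0).
#' @param i0 Total ligand concentration.
#' @return A one-row tibble with columns `pi` (complex concentration),
#'   `theta` (fractional occupancy) and `excess_fold` (`i0 / p0`).
#' @examples
#' complex_concentration(kd = 11.2, p0 = 100, i0 = 1188)  # theta ~ 0.99
#' @export
complex_concentration <- function(kd, p0, i0) {
  if (any(c(kd, p0, i0) < 0) || any(!is.finite(c(kd, p0, i0)))) {
    abort("kd, p0 and i0 must be finite and >= 0")
  }
  if (p0 <= 0) abort("p0 must be > 0")
  s <- p0 + i0 + kd
  disc <- sqrt(pmax(s^2 - 4 * p0 * i0, 0))
  pi_ <- if (s + disc > 0) 2 * p0 * i0 / (s + disc) else 0
  pi_ <- min(pi_, p0, i0)
  tibble::tibble(pi = pi_, theta = pi_ / p0, excess_fold = i0 / p0)
}

#' Ligand concentration required for a target occupancy
#'
#' Inverts the quadratic 1:1 binding relation in closed form: the smallest
#' total ligand concentration achieving occupancy `theta` is
#' `I0 = theta * P0 + theta * KD / (1 - theta)`.
#'
#' @inheritParams complex_concentration
#' @param theta_target Desired fractional occupancy, strictly in (0, 1).
#' @return Required total ligand concentration (same units as inputs).
#' @examples
#' ligand_for_occupancy(kd = 11.2, p0 = 100, theta_target = 0.99)
#' @export
ligand_for_occupancy <- function(kd, p0, theta_target) {
  if (any(c(kd, p0) < 0) || p0 <= 0) abort("kd >= 0 and p0 > 0 required")
  if (theta_target >= 1) {
    abort("theta_target >= 1 is unreachable at finite ligand when kd > 0")
  }
  if (theta_target <= 0) abort("theta_target must be in (0, 1)")
  theta_target * p0 + theta_target * kd / (1 - theta_target)
}

#' Bound/unbound mixture weights at a given occupancy
#'
#' @param theta Fractional occupancy in \[0, 1\], or the tibble returned by
#'   [complex_concentration()].
#' @return A named numeric vector `c(bound = theta, unbound = 1 - theta)`.
#' @export
occupancy_mixture_weights <- function(theta) {
  if (is.data.frame(theta)) theta <- theta$theta
  stopifnot(length(theta) == 1, theta >= 0, theta <= 1)
  c(bound = theta, unbound = 1 - theta)
}
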