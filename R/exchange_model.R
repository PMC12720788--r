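#' EX2 observed exchange rate
#'
#' In the EX2 regime (intrinsic exchange much slower than refolding,
#' `k_int << k_close`) an amide opens and recloses many times before
#' exchanging, and the observed rate is the opening equilibrium constant
#' times the intrinsic rate: `k_HDX = (k_open / k_close) * k_int`.
#'
#' @param k_int Intrinsic exchange rate of the open state, 1/s.
#' @param k_open Opening rate, 1/s.
#' @param k_close Closing rate, 1/s; must be positive.
#' @return Observed exchange rate in 1/s (vectorised).
#' @examples
#' ex2_rate(k_int = 0.1, k_open = 1e-3, k_close = 10)  # 1e-5
#' @export
ex2_rate <- function(k_int, k_open, k_close) {
  check_rates(k_int, k_open, k_close)
  if (any(k_close == 0)) {
    abort("k_close = 0: EX2 rate K_op * k_int is undefined (K_op infinite)")
  }
  (k_open / k_close) * k_int
}

check_rates <- function(k_int, k_open, k_close) {
  if (any(!is.finite(k_int)) || any(!is.finite(k_open)) || any(!is.finite(k_close)) ||
      any(k_int < 0) || any(k_open < 0) || any(k_close < 0)) {
    abort("Rates must be finite and >= 0")
  }
  invisible(TRUE)
}

# eigenvalues of the closed <-> open -> exchanged chain; returns the slow
# (lambda1) and fast (lambda2) decay rates as positive numbers, in a
# subtraction-safe form: lambda1 = 2*k_open*k_int / (s + sqrt(s^2 - 4ac)).
exchange_eigenrates <- function(k_int, k_open, k_close) {
  s <- k_open + k_close + k_int
  ac <- k_open * k_int
  disc <- sqrt(pmax(s^2 - 4 * ac, 0))
  fast <- (s + disc) / 2
  slow <- ifelse(fast > 0, ac / fast, 0)
  list(slow = slow, fast = fast)
}

#' Effective (slow-phase) exchange rate of the two-state model
#'
#' The slow eigenvalue of the linear kinetics closed <-> open -> exchanged,
#' i.e. the long-time decay rate of the unexchanged population. Approaches
#' `K_op * k_int` in the EX2 limit and `k_open` in the EX1 limit.
#'
#' @inheritParams ex2_rate
#' @return Effective exchange rate, 1/s (vectorised).
#' @export
effective_exchange_rate <- function(k_int, k_open, k_close) {
  check_rates(k_int, k_open, k_close)
  exchange_eigenrates(k_int, k_open, k_close)$slow
}

#' Probability that an amide has exchanged by time t
#'
#' Closed-form solution of the Linderstrom-Lang two-state scheme
#' closed <-> open -> exchanged, starting closed: the survival (unexchanged)
#' probability is a two-exponential mixture of the chain's eigenmodes, and
#' the exchange probability is its complement. Valid in both EX1 and EX2
#' regimes and for irreversible opening (`k_close = 0`).
#'
#' @param t Exposure time(s), seconds, >= 0.
#' @inheritParams ex2_rate
#' @return Exchange probabilities in \[0, 1\], vectorised over `t` or over
#'   the rate arguments (lengths recycled).
#' @examples
#' exchange_probability(1e5, k_int = 0.1, k_open = 1e-3, k_close = 10)
#' @export
exchange_probability <- function(t, k_int, k_open, k_close) {
  if (any(!is.finite(t)) || any(t < 0)) abort("t must be finite and >= 0")
  check_rates(k_int, k_open, k_close)
  n <- max(length(t), length(k_int), length(k_open), length(k_close))
  t <- rep_len(t, n); k_int <- rep_len(k_int, n)
  k_open <- rep_len(k_open, n); k_close <- rep_len(k_close, n)
  eig <- exchange_eigenrates(k_int, k_open, k_close)
  l1 <- eig$slow; l2 <- eig$fast
  sep <- (l2 - l1) > 1e-12 * l2
  surv <- numeric(n)
  # generic two-eigenvalue form; weights from S(0) = 1, S'(0) = 0
  i <- sep
  surv[i] <- (l2[i] * exp(-l1[i] * t[i]) - l1[i] * exp(-l2[i] * t[i])) /
    (l2[i] - l1[i])
  # (near-)repeated root: critically damped limit (1 + l*t) exp(-l*t)
  j <- !sep
  surv[j] <- (1 + l2[j] * t[j]) * exp(-l2[j] * t[j])
  pmin(pmax(1 - surv, 0), 1)
}

#' Stochastic oracle for the two-state exchange model
#'
#' Event-driven simulation of `n_molecules` independent amides through the
#' closed <-> open -> exchanged chain. Each molecule survives a geometric
#' number of opening events before exchanging (per-opening exchange
#' probability `k_int / (k_int + k_close)`); its exchange time is the sum of
#' the corresponding gamma-distributed closed and open waiting times. Used
#' to validate [exchange_probability()] against an independent sampling
#' route.
#'
#' @inheritParams ex2_rate
#' @param t Exposure time, seconds.
#' @param n_molecules Number of simulated molecules.
#' @return Empirical fraction of molecules exchanged by `t`.
#' @export
stochastic_exchange_fraction <- function(t, k_int, k_open, k_close,
                                         n_molecules = 1e5) {
  stopifnot(length(t) == 1, t >= 0, n_molecules >= 1)
  check_rates(k_int, k_open, k_close)
  if (k_open == 0 || k_int == 0) return(0)
  p_exch <- k_int / (k_int + k_close)
  n_open <- rgeom(n_molecules, p_exch) + 1L   # openings until exchange
  t_closed <- rgamma(n_molecules, shape = n_open, rate = k_open)
  t_open <- rgamma(n_molecules, shape = n_open, rate = k_int + k_close)
  mean(t_closed + t_open <= t)
}

#' Isotope-envelope model for a peptide at one exposure time
#'
#' Returns the distribution of added deuterons (unit-mass channels
#' `0..n_residues`). In EX2 mode residues exchange independently and the
#' envelope is the Poisson-binomial convolution of the per-residue exchange
#' probabilities: unimodal, with centroid equal to the summed probabilities.
#' In EX1 mode all residues in the block exchange together on the first
#' opening of a single shared clock with rate `k_open`, giving a bimodal
#' mixture of an undeuterated-like and a fully-deuterated-like population
#' with weights `exp(-k_open t)` and `1 - exp(-k_open t)`.
#'
#' @param params A data frame with columns `k_int`, `k_open`, `k_close`, one
#'   row per exchangeable residue.
#' @param t Exposure time, seconds.
#' @param mode `"EX2"` (independent residues) or `"EX1"` (shared opening).
#' @return A tibble with columns `n_deuterons` (0..n) and `intensity`
#'   (sums to 1).
#' @export
simulate_envelope <- function(params, t, mode = c("EX2", "EX1")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(params))
  if (nrow(params) == 0) abort("Need at least one residue")
  check_rates(params$k_int, params$k_open, params$k_close)
  n <- nrow(params)
  if (mode == "EX2") {
    p <- exchange_probability(t, params$k_int, params$k_open, params$k_close)
    intensity <- 1
    for (pi in p) intensity <- convolve_bernoulli(intensity, pi)
  } else {
    w_open <- 1 - exp(-params$k_open[1] * t)
    intensity <- numeric(n + 1)
    intensity[1] <- 1 - w_open
    intensity[n + 1] <- intensity[n + 1] + w_open
  }
  tibble::tibble(n_deuterons = 0:n, intensity = intensity)
}

convolve_bernoulli <- function(dist, p) {
  c(dist * (1 - p), 0) + c(0, dist * p)
}

#' Envelope centroid (mean added deuterons)
#'
#' @param envelope Output of [simulate_envelope()].
#' @return Intensity-weighted mean number of added deuterons.
#' @export
envelope_centroid <- function(envelope) {
  sum(envelope$n_deuterons * envelope$intensity) / sum(envelope$intensity)
}
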