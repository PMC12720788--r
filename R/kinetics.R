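#' Fit a one-exponential uptake curve
#'
#' Fits `D(t) = A * (1 - exp(-k * t))` to a deuterium uptake time course by
#' bounded nonlinear least squares (Levenberg-Marquardt). Replicates enter
#' as individual points with uniform weight; time-zero points are exact
#' anchors (the model passes through zero by construction). Initial values
#' are `A0 = max(uptake)` and `k0 = ln 2 / t_half`, where `t_half` is the
#' earliest time reaching half of `A0` (median time if none does). `k` is
#' constrained to (1e-6, 10) 1/s and `A` to (0, 1.2 * max uptake];
#' `converged` is `FALSE` if the optimizer stops on a bound or the
#' iteration cap.
#'
#' @param data A data frame with columns `exposure_s` and an uptake column
#'   (`relative_uptake_pct` by default), e.g. one peptide x state subset of
#'   an uptake-record tibble.
#' @param response Name of the uptake column to fit.
#' @return An object of class `hdx_fit` with elements `amplitude`, `k_hdx`
#'   (1/s), `k_hdx_per_min` (= 60 * k_hdx), `se_k`, `sse`, `converged`,
#'   `n_points`, and the fitted model. Supports [tidy()], [glance()] and
#'   `predict()`.
#' @examples
#' t <- c(0, 30, 90, 300, 1800, 3600, 5400)
#' d <- data.frame(exposure_s = t,
#'                 relative_uptake_pct = 80 * (1 - exp(-0.01 * t)))
#' fit_one_exponential(d)
#' @export
fit_one_exponential <- function(data, response = "relative_uptake_pct") {
  stopifnot(is.data.frame(data), "exposure_s" %in% names(data),
            response %in% names(data))
  t <- data$exposure_s
  y <- data[[response]]
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    abort("Non-finite time or uptake value in curve data")
  }
  nz <- unique(t[t > 0])
  if (length(nz) < 3) abort("Need >= 3 distinct non-zero timepoints to fit")
  if (all(y[t > 0] <= 0)) abort("All-zero uptake: no exchange signal to fit")

  a0 <- max(y)
  half_idx <- which(t > 0 & y >= a0 / 2)
  t_half <- if (length(half_idx)) min(t[half_idx]) else median(nz)
  k0 <- min(max(log(2) / t_half, 2e-6), 9)
  a_hi <- 1.2 * max(y)

  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ A * (1 - exp(-k * t)), data = df,
    start = list(A = a0, k = k0),
    lower = c(A = 1e-12, k = 1e-6), upper = c(A = a_hi, k = 10),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(A = NA, k = NA))
  # time-zero anchors are exact (no noise enters them), so the residual
  # variance must be scaled over the informative points only
  n_pos <- sum(t > 0)
  if (n_pos > 2 && length(t) > n_pos) {
    se <- se * sqrt((length(t) - 2) / (n_pos - 2))
  }
  on_bound <- est[["k"]] <= 1e-6 * (1 + 1e-6) || est[["k"]] >= 10 * (1 - 1e-6) ||
    est[["A"]] >= a_hi * (1 - 1e-9)
  info <- fit$convInfo
  converged <- isTRUE(info$isConv) && !on_bound

  structure(list(
    amplitude = unname(est[["A"]]), k_hdx = unname(est[["k"]]),
    k_hdx_per_min = 60 * unname(est[["k"]]),
    se_k = unname(se[["k"]]), se_amplitude = unname(se[["A"]]),
    sse = sum(residuals(fit)^2), converged = converged,
    n_points = length(t), response = response, model = fit,
    data = tibble::tibble(exposure_s = t, uptake = y)
  ), class = "hdx_fit")
}

#' @export
print.hdx_fit <- function(x, ...) {
  cat(sprintf(
    "One-exponential uptake fit: A = %.4g, k = %.4g 1/s (%.4g 1/min), SE(k) = %.2g%s\n",
    x$amplitude, x$k_hdx, x$k_hdx_per_min, x$se_k,
    if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
predict.hdx_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$exposure_s else newdata$exposure_s
  object$amplitude * (1 - exp(-object$k_hdx * t))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a one-exponential uptake fit
#'
#' @param x An `hdx_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.hdx_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "k_hdx"),
    estimate = c(x$amplitude, x$k_hdx),
    std.error = c(x$se_amplitude, x$se_k)
  )
}

#' One-row summary of a one-exponential uptake fit
#'
#' @param x An `hdx_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with amplitude, rates in both units, SE, SSE,
#'   point count and convergence flag.
#' @export
glance.hdx_fit <- function(x, ...) {
  tibble::tibble(
    amplitude = x$amplitude, k_hdx = x$k_hdx,
    k_hdx_per_min = x$k_hdx_per_min, se_k = x$se_k, sse = x$sse,
    n_points = x$n_points, converged = x$converged
  )
}

#' Fit uptake curves for every peptide x state
#'
#' @param records An uptake-record tibble.
#' @param response Uptake column to fit.
#' @return A tibble with one row per peptide x state, the glance columns of
#'   each fit, and a `rate_class` label.
#' @export
fit_uptake_curves <- function(records, response = "relative_uptake_pct") {
  records |>
    dplyr::group_by(.data$protein, .data$start, .data$end, .data$sequence,
                    .data$state) |>
    dplyr::group_modify(function(d, key) {
      glance(fit_one_exponential(d, response = response))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(rate_class = rate_class(.data$k_hdx_per_min)) |>
    dplyr::arrange(.data$start, .data$end, .data$state)
}

#' Opening equilibrium constant from an observed EX2 rate
#'
#' Inverts the EX2 relation `k_HDX = K_op * k_int`. Valid only when the
#' caller has established EX2 exchange; `k_hdx > k_int` would imply
#' `K_op > 1` (an unprotected amide) and is rejected as a regime violation.
#'
#' @param k_hdx Observed exchange rate, 1/s.
#' @param k_int Intrinsic exchange rate, 1/s (> 0).
#' @return `K_op = k_hdx / k_int` (dimensionless); its reciprocal is the
#'   protection factor.
#' @export
kop_from_ex2 <- function(k_hdx, k_int) {
  stopifnot(all(is.finite(k_hdx)), all(is.finite(k_int)))
  if (any(k_int <= 0)) abort("k_int must be > 0")
  if (any(k_hdx < 0)) abort("k_hdx must be >= 0")
  if (any(k_hdx > k_int)) {
    abort("k_hdx > k_int implies K_op > 1: incompatible with a protected amide (EX2 regime violated)")
  }
  k_hdx / k_int
}

#' Classify an exchange rate as fast, intermediate or slow
#'
#' Thresholds follow the common description of amide exchange classes on
#' the minute scale and are a convention, not a measured quantity: fast
#' >= 10 1/min, intermediate in \[0.05, 10), slow below 0.05 1/min.
#'
#' @param k_hdx_per_min Observed rate(s), 1/min.
#' @param thresholds Length-2 numeric: c(slow/intermediate, intermediate/fast).
#' @return Character vector of labels.
#' @examples
#' rate_class(c(0.31, 2.68, 20))
#' @export
rate_class <- function(k_hdx_per_min, thresholds = c(0.05, 10)) {
  stopifnot(all(k_hdx_per_min >= 0), length(thresholds) == 2,
            thresholds[1] < thresholds[2])
  dplyr::case_when(
    k_hdx_per_min >= thresholds[2] ~ "fast",
    k_hdx_per_min >= thresholds[1] ~ "intermediate",
    .default = "slow"
  )
}

#' Compare two fitted exchange rates
#'
#' Rate ratio `k_B / k_A` with an approximate standard error propagated
#' from the two fits (delta method on log rates); the verdict is
#' `"distinct"` when the ratio's +/- 2 SE interval excludes 1.
#'
#' @param fit_a,fit_b Converged `hdx_fit` objects.
#' @return A one-row tibble: `ratio`, `se_ratio`, `distinct`.
#' @export
compare_fits <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "hdx_fit"), inherits(fit_b, "hdx_fit"))
  if (!fit_a$converged || !fit_b$converged) {
    abort("Both fits must have converged to be compared")
  }
  ratio <- fit_b$k_hdx / fit_a$k_hdx
  # delta method: var(log ratio) = (se_a/k_a)^2 + (se_b/k_b)^2
  se_log <- sqrt((fit_a$se_k / fit_a$k_hdx)^2 + (fit_b$se_k / fit_b$k_hdx)^2)
  se_ratio <- ratio * se_log
  lo <- ratio * exp(-2 * se_log); hi <- ratio * exp(2 * se_log)
  tibble::tibble(ratio = ratio, se_ratio = se_ratio,
                 distinct = (lo > 1) | (hi < 1))
}
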