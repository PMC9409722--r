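#' Closed-form speckle contrast for a given exposure and decorrelation time
#'
#' Under a Lorentzian field correlation `g1(t) = exp(-t / tau_c)` (the
#' model the simulator implements) the spatial contrast of a frame
#' integrated over exposure T has the closed form
#' \deqn{K(T, \tau_c) = \sqrt{\beta \left[ \frac{\tau_c}{T} +
#'   \frac{\tau_c^2}{2 T^2}\left(e^{-2T/\tau_c} - 1\right) \right]}}{
#'   K = sqrt(beta * (tau/T + tau^2/(2 T^2) (exp(-2T/tau) - 1)))}
#' It is strictly increasing in `tau_c` at fixed `T`, tends to
#' `sqrt(beta)` as `T/tau_c -> 0` (static limit) and to 0 as
#' `T/tau_c -> Inf` (full blur). This is the oracle the simulator is
#' validated against; it is not claimed to describe any particular tissue.
#'
#' @param exposure_ms Exposure time T in ms (positive; vectorized).
#' @param tau_c_ms Decorrelation time tau_c in ms (positive; vectorized).
#' @param beta Coherence factor in (0, 1].
#' @return Contrast value(s) in `[0, sqrt(beta)]`.
#' @export
theoretical_contrast <- function(exposure_ms, tau_c_ms, beta = 1) {
  if (any(exposure_ms <= 0)) stop("`exposure_ms` must be positive")
  if (any(tau_c_ms <= 0)) stop("`tau_c_ms` must be positive")
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]")
  x <- exposure_ms / tau_c_ms
  f <- ifelse(x < 1e-4,
              1 - 2 * x / 3 + x^2 / 3,          # series, avoids cancellation
              (2 * x + exp(-2 * x) - 1) / (2 * x^2))
  sqrt(beta * f)
}

#' Invert the contrast-vs-exposure relation for the decorrelation time
#'
#' Finds the unique decorrelation time tau_c at which
#' [theoretical_contrast()] equals a measured contrast, by bracketed root
#' finding over `tau_c in [1e-6 T, 1e6 T]` to a relative tolerance of
#' 1e-9. Contrasts at or above `sqrt(beta)` have no finite solution and
#' are rejected, as are non-positive contrasts or contrasts below the
#' value attainable at the lower bracket end.
#'
#' @param k Measured speckle contrast, `0 < k < sqrt(beta)`.
#' @param exposure_ms Exposure time T in ms.
#' @param beta Coherence factor in (0, 1]; use the simulator's calibrated
#'   [calibrate_beta()] value when inverting simulated measurements.
#' @return Estimated `tau_c` in ms.
#' @export
estimate_tau_c <- function(k, exposure_ms, beta = 1) {
  if (length(k) != 1 || !is.finite(k)) stop("`k` must be a finite scalar")
  if (exposure_ms <= 0) stop("`exposure_ms` must be positive")
  if (k <= 0) stop("`k` must be positive")
  if (k >= sqrt(beta))
    stop(sprintf("k = %.6g >= sqrt(beta) = %.6g: no finite tau_c", k, sqrt(beta)))
  lo <- 1e-6 * exposure_ms
  hi <- 1e6 * exposure_ms
  g <- function(tau) theoretical_contrast(exposure_ms, tau, beta) - k
  if (g(lo) > 0)
    stop("`k` below the contrast attainable at tau_c = 1e-6 * T")
  stats::uniroot(g, c(lo, hi), tol = 1e-9 * exposure_ms,
                 extendInt = "no")$root
}
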