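#' Gamma-variate arterial input function
#'
#' Constructs the bolus model used by the digital phantom: a gamma-variate
#' concentration-time curve
#' \deqn{c(t) = A (t - t_0)^\alpha \exp(-(t - t_0)/\beta), \quad t > t_0,}
#' and zero before bolus arrival. The gamma variate is the standard
#' parametric description of a first-pass contrast bolus through a large
#' feeding artery.
#'
#' With `amplitude = NULL` the curve is peak-normalized: the amplitude is set
#' to the closed form `1 / ((alpha*beta)^alpha * exp(-alpha))` so that the
#' maximum, attained at `t = t0 + alpha*beta`, equals 1 concentration unit.
#'
#' @param t0 Bolus arrival time in seconds (non-negative).
#' @param alpha Gamma shape parameter (> 0, dimensionless).
#' @param beta Gamma scale parameter in seconds (> 0).
#' @param amplitude Curve amplitude in concentration units, or `NULL` for a
#'   peak-normalized curve.
#' @return An object of class `aif_model`.
#' @examples
#' a <- aif_model()
#' t <- seq(0, 48, by = 1.5)
#' plot(t, eval_aif(a, t), type = "l")
#' @export
aif_model <- function(t0 = 6, alpha = 3, beta = 1.5, amplitude = NULL) {
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  if (!is.numeric(beta) || beta <= 0) stop("'beta' must be > 0")
  if (!is.numeric(t0) || t0 < 0) stop("'t0' must be >= 0")
  if (is.null(amplitude)) amplitude <- 1 / ((alpha * beta)^alpha * exp(-alpha))
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude),
            class = "aif_model")
}

#' Evaluate an arterial input function on a time grid
#'
#' @param aif An [aif_model()].
#' @param t Non-decreasing numeric vector of times in seconds.
#' @return Concentration vector of the same length as `t`; zero for
#'   `t <= t0`, non-negative and finite everywhere.
#' @export
eval_aif <- function(aif, t) {
  stopifnot(inherits(aif, "aif_model"))
  if (is.unsorted(t)) stop("'t' must be non-decreasing")
  u <- t - aif$t0
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- aif$amplitude * u[pos]^aif$alpha * exp(-u[pos] / aif$beta)
  out
}

#' Tissue kinetics obeying the central volume principle
#'
#' Bundles cerebral blood flow (CBF, mL/100 mL/min) and cerebral blood volume
#' (CBV, mL/100 mL); the mean transit time (MTT, s) is derived exactly from
#' the central volume principle `mtt = 60 * cbv / cbf`.
#'
#' @param cbf Cerebral blood flow in mL/100 mL/min (> 0).
#' @param cbv Cerebral blood volume in mL/100 mL (> 0).
#' @return An object of class `tissue_kinetics` with fields `cbf`, `cbv`,
#'   `mtt`.
#' @export
tissue_kinetics <- function(cbf, cbv) {
  if (!is.numeric(cbf) || cbf <= 0) stop("'cbf' must be > 0")
  if (!is.numeric(cbv) || cbv <= 0) stop("'cbv' must be > 0")
  structure(list(cbf = cbf, cbv = cbv, mtt = 60 * cbv / cbf),
            class = "tissue_kinetics")
}

#' Exponential residue function
#'
#' Fraction of tracer still present in a voxel `t` seconds after an idealized
#' instantaneous arterial input: `R(t) = exp(-t / mtt)`. The mono-exponential
#' form is the simplest residue consistent with the central volume principle
#' (its integral equals the mean transit time).
#'
#' @param t Non-negative time(s) in seconds.
#' @param kinetics A [tissue_kinetics()].
#' @return Values in (0, 1].
#' @export
residue <- function(t, kinetics) {
  stopifnot(inherits(kinetics, "tissue_kinetics"))
  if (any(t < 0)) stop("'t' must be >= 0")
  exp(-t / kinetics$mtt)
}

# Trapezoid-quadrature discrete convolution of two curves sampled on a uniform
# grid: out[i] ~ integral_0^{t_i} a(s) k(t_i - s) ds. FFT-based; the trapezoid
# end-point corrections keep the discrete curve mass-conserving (a rectangle
# rule biases the integral by ~dt/(2*mtt)).
conv_uniform <- function(a, k, dt) {
  n <- length(a)
  if (length(k) != n) stop("grid lengths differ")
  full <- convolve(a, rev(k), type = "open")[seq_len(n)] * dt
  i <- seq_len(n)
  full - dt * 0.5 * (a[1] * k[i] + a[i] * k[1])
}

#' Tissue concentration-time curve from the indicator-dilution model
#'
#' Computes the tissue response
#' \deqn{C(t) = \frac{CBF}{6000} \, (AIF \ast R)(t)}
#' by discrete convolution (trapezoid quadrature) of the arterial input with
#' the exponential residue on the given uniform time grid. The factor 1/6000
#' converts CBF from mL/100 mL/min into a per-second, per-unit-volume rate,
#' so that the indicator-dilution identity
#' `integral(C) = (cbv/100) * integral(AIF)` holds up to discretization error.
#'
#' @param aif An [aif_model()].
#' @param kinetics A [tissue_kinetics()].
#' @param t Uniform, increasing time grid in seconds.
#' @return Concentration vector of the same length as `t`.
#' @export
tissue_curve <- function(aif, kinetics, t) {
  stopifnot(inherits(aif, "aif_model"), inherits(kinetics, "tissue_kinetics"))
  if (length(t) < 2) stop("'t' must have at least two points")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) stop("'t' must be a uniform grid")
  a <- eval_aif(aif, t)
  r <- residue(t - t[1], kinetics)
  (kinetics$cbf / 6000) * conv_uniform(a, r, dt[1])
}
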