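## Empirical meal rate-of-appearance (Ra) functions.
##
## During a mixed meal, glucose and FFA enter the circulation from the
## gut.  Rather than modelling gastric emptying and absorption
## mechanistically, the appearance flux is parameterised by simple
## smooth functions: a log-normal-like form ("Type I", 3 parameters for
## glucose, with a fixed chylomicron lag for FFA) and a Rayleigh-like
## form ("Type II", 2 parameters, glucose only).

#' Type I (log-normal-like) glucose rate of appearance
#'
#' \deqn{Ra_G(t) = \frac{\Delta_G}{t\,\sigma_G}
#'   \exp\left(-\frac{[\ln(t/m_G)]^2}{2\sigma_G^2}\right)}
#' with \eqn{Ra_G(0) = 0}.  The total area under the curve is
#' \eqn{\Delta_G \sqrt{2\pi}} and the maximum sits at
#' \eqn{t = m_G e^{-\sigma_G^2}}.
#'
#' @param Delta_G magnitude factor (mg/dL, phenomenological).
#' @param m_G time-scale parameter (min).
#' @param sigma_G dimensionless width parameter.
#' @return an `ffamm_ra` object; evaluate with [ra_eval()] or [ra_fun()].
#' @export
ra_type1_glucose <- function(Delta_G, m_G, sigma_G) {
  if (Delta_G < 0) stop("Delta_G must be non-negative")
  if (m_G <= 0 || sigma_G <= 0) stop("m_G and sigma_G must be positive")
  structure(list(Delta = Delta_G, m = m_G, sigma = sigma_G, t0 = 0),
            class = c("ra_type1", "ffamm_ra"))
}

#' Type I (log-normal-like) FFA rate of appearance
#'
#' Same functional form as [ra_type1_glucose()] but in shifted time
#' `t - t_0F`: FFA originating from chylomicron triglyceride does not
#' appear in plasma before the lag `t_0F`, so `Ra_F(t) = 0` for
#' `t <= t_0F`.  The lag and time scale are fixed (`t_0F = 60` min,
#' `m_F = 300` min) by convention.
#'
#' @param Delta_F magnitude factor (mmol/L).
#' @param sigma_F dimensionless width parameter.
#' @param m_F time-scale parameter (min), fixed at 300 by default.
#' @param t_0F chylomicron lag time (min), fixed at 60 by default.
#' @return an `ffamm_ra` object.
#' @export
ra_type1_ffa <- function(Delta_F, sigma_F, m_F = 300, t_0F = 60) {
  if (Delta_F < 0) stop("Delta_F must be non-negative")
  if (m_F <= 0 || sigma_F <= 0) stop("m_F and sigma_F must be positive")
  if (t_0F < 0) stop("t_0F must be non-negative")
  structure(list(Delta = Delta_F, m = m_F, sigma = sigma_F, t0 = t_0F),
            class = c("ra_type1", "ffamm_ra"))
}

#' Type II (Rayleigh-like) glucose rate of appearance
#'
#' \deqn{Ra_G(t) = \frac{\phi_G\, t}{\tau_G^2}
#'   \exp\left(-\frac{t^2}{2\tau_G^2}\right)}
#' a two-parameter alternative to the Type I form.  Its total area is
#' exactly \eqn{\phi_G} and its maximum sits at \eqn{t = \tau_G}.
#'
#' @param phi_G magnitude coefficient (mg/dL).
#' @param tau_G timescale coefficient (min).
#' @return an `ffamm_ra` object.
#' @export
ra_type2_glucose <- function(phi_G, tau_G) {
  if (phi_G < 0) stop("phi_G must be non-negative")
  if (tau_G <= 0) stop("tau_G must be positive")
  structure(list(phi = phi_G, tau = tau_G),
            class = c("ra_type2", "ffamm_ra"))
}

#' Evaluate a rate-of-appearance function
#'
#' @param ra an `ffamm_ra` object.
#' @param t time(s) (min), non-negative.
#' @return Ra value(s) (concentration/min).
#' @export
ra_eval <- function(ra, t) UseMethod("ra_eval")

#' @export
ra_eval.ra_type1 <- function(ra, t) {
  if (any(t < 0)) stop("t must be non-negative")
  ts <- t - ra$t0
  out <- numeric(length(t))
  pos <- ts > 0
  if (any(pos)) {
    z <- log(ts[pos] / ra$m)
    out[pos] <- ra$Delta / (ts[pos] * ra$sigma) *
      exp(-z^2 / (2 * ra$sigma^2))
  }
  out
}

#' @export
ra_eval.ra_type2 <- function(ra, t) {
  if (any(t < 0)) stop("t must be non-negative")
  ra$phi * t / ra$tau^2 * exp(-t^2 / (2 * ra$tau^2))
}

#' @rdname ra_eval
#' @return `ra_fun` returns a plain function of time.
#' @export
ra_fun <- function(ra) function(t) ra_eval(ra, t)

## time of the Ra maximum (used for AUC truncation)
ra_peak_time <- function(ra) {
  if (inherits(ra, "ra_type2")) return(ra$tau)
  ra$t0 + ra$m * exp(-ra$sigma^2)
}

#' Area under a rate-of-appearance curve
#'
#' Integrates an Ra function over `[t_start, t_end]` by adaptive
#' quadrature (absolute tolerance `1e-8`).  An infinite upper limit is
#' truncated at the point where the integrand has fallen below
#' `1e-12` of its peak value, which bounds the discarded tail well
#' below the quadrature tolerance for these forms.
#'
#' @param ra an `ffamm_ra` object (or plain function of time).
#' @param t_start,t_end integration limits (min), `t_start < t_end`;
#'   `t_end` may be `Inf`.
#' @return the AUC (concentration units).
#' @export
ra_auc <- function(ra, t_start = 0, t_end = Inf) {
  if (!is.finite(t_start) || t_start < 0)
    stop("t_start must be finite and non-negative")
  if (t_start >= t_end) stop("t_start must be smaller than t_end")
  f <- if (inherits(ra, "ffamm_ra")) ra_fun(ra) else ra
  if (is.infinite(t_end)) {
    if (inherits(ra, "ffamm_ra")) {
      tp <- ra_peak_time(ra)
      fp <- f(max(tp, t_start, 1e-6))
      if (fp <= 0) return(0)
      hi <- max(tp, t_start, 1)
      while (f(hi) > 1e-12 * fp) hi <- hi * 2
      t_end <- hi
    } else stop("infinite t_end requires an ffamm_ra object")
  }
  integrate(f, t_start, t_end, abs.tol = 1e-8, rel.tol = 1e-10,
            subdivisions = 1000L)$value
}
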