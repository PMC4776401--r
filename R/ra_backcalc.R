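## Back-calculation of glucose rate of appearance from meal-test data.
##
## Rearranging the minimal-model glucose equation gives the appearance
## flux directly from the measured glucose and the simulated insulin
## action:
##   Ra(t) = dG/dt - S_G * G_b + (S_G + S_I * X(t)) * G(t)
## with dG/dt approximated by a cubic spline through the sparse meal
## samples on a 1-min grid.  No positivity constraint is applied, so
## spline artifacts near steep segments show up as negative excursions.

#' Cubic-spline interpolation of a series with derivatives
#'
#' Fits a cubic interpolating spline through the samples and evaluates
#' it, together with its analytic first derivative, on a dense grid
#' spanning the sampled range.  Forsythe-Malcolm-Moler end conditions
#' are used (the exact cubic through the four points nearest each end):
#' natural end conditions force zero curvature at t = 0, exactly where
#' the meal appearance flux has its steepest ramp, and roughly double
#' the boundary derivative error on sparsely sampled meal data.
#'
#' @param series a [sampled_series()] with at least 4 samples.
#' @param grid_step grid spacing (min), default 1.
#' @return a `data.frame` with columns `time`, `value`, `deriv`.
#' @export
spline_series <- function(series, grid_step = 1) {
  s <- as_series(series)
  if (nrow(s) < 4L) stop("spline interpolation needs at least 4 samples")
  sf <- splinefun(s$time, s$value, method = "fmm")
  grid <- seq(s$time[1L], s$time[nrow(s)], by = grid_step)
  data.frame(time = grid, value = sf(grid), deriv = sf(grid, deriv = 1))
}

#' Back-calculate glucose rate of appearance in the meal test
#'
#' @param glucose_mt measured meal-test glucose series.
#' @param X simulated insulin action: either a trajectory from
#'   [simulate_model()] (columns `time`, `X`) or a two-column
#'   time/value object.  Must cover the glucose time range; values are
#'   linearly interpolated onto the spline grid.
#' @param S_G,S_I,G_b glucose-equation parameters from a prior fit.
#' @param grid_step grid spacing (min), default 1.
#' @return a `data.frame` with columns `time`, `Ra`, `G_spline`,
#'   `dGdt`, `X`.
#' @export
backcalc_ra <- function(glucose_mt, X, S_G, S_I, G_b, grid_step = 1) {
  sp <- spline_series(glucose_mt, grid_step = grid_step)
  if (is.data.frame(X) && all(c("time", "X") %in% names(X)))
    xs <- sampled_series(X$time, X$X)
  else xs <- as_series(X, "insulin action")
  if (xs$time[1L] > sp$time[1L] + 1e-9 ||
      xs$time[nrow(xs)] < sp$time[nrow(sp)] - 1e-9)
    stop("insulin-action record does not cover the glucose time range")
  xf <- approxfun(xs$time, xs$value)
  Xg <- xf(sp$time)
  ra <- sp$deriv - S_G * G_b + (S_G + S_I * Xg) * sp$value
  data.frame(time = sp$time, Ra = ra, G_spline = sp$value,
             dGdt = sp$deriv, X = Xg)
}
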