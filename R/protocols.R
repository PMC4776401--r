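## Tolerance-test protocols and model integration.

FSIGT_TIMES <- c(-10, -1, 0, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12, 14, 16, 20,
                 22, 23, 24, 25, 27, 30, 40, 50, 60, 70, 80, 90, 100,
                 120, 150, 180)
MT_TIMES <- seq(0, 360, by = 30)

#' Tolerance-test protocols
#'
#' Returns the sampling schedule and fitting window of a protocol.
#' The IM-FSIGT draws 32 samples between -10 and 180 min (dense early
#' sampling around the glucose bolus at 0 min and the insulin bolus at
#' 20 min); only data in \[10, 180\] min are fitted, with initial values
#' taken as the average of the 0-8 min samples.  The meal test samples
#' every 30 min from 0 to 360 min and is fitted over the whole window.
#'
#' @param kind `"FSIGT"` or `"MT"`.
#' @return an object of class `ffamm_protocol` with elements `kind`,
#'   `sample_times` and `fit_window`.
#' @export
protocol <- function(kind = c("FSIGT", "MT")) {
  kind <- match.arg(kind)
  if (kind == "FSIGT")
    structure(list(kind = kind, sample_times = FSIGT_TIMES,
                   fit_window = c(10, 180)), class = "ffamm_protocol")
  else
    structure(list(kind = kind, sample_times = MT_TIMES,
                   fit_window = c(0, 360)), class = "ffamm_protocol")
}

## sample times that enter the residual sum for a protocol
fit_times <- function(prot) {
  st <- prot$sample_times
  st[st >= prot$fit_window[1] & st <= prot$fit_window[2]]
}

#' Initial state for a protocol simulation
#'
#' Insulin action starts at zero in both protocols.  For the meal test,
#' glucose and FFA start at their measured values at t = 0.  For the
#' IM-FSIGT, integration starts at t = 10 min and the initial glucose
#' and FFA are the averages of the measurements in \[0, 10) min (the
#' 0-8 min samples), so the t = 10 sample remains an ordinary fitted
#' datum.
#'
#' @param prot a protocol from [protocol()].
#' @param subject an `ffamm_subject`.
#' @param channels channels to initialise (default glucose and ffa;
#'   MOD 3 needs only `"ffa"`).
#' @return named state vector `c(G=, X=0, F=)` (entries restricted to
#'   the requested channels).
#' @export
initial_conditions <- function(prot, subject,
                               channels = c("glucose", "ffa")) {
  stopifnot(inherits(prot, "ffamm_protocol"),
            inherits(subject, "ffamm_subject"))
  block <- subject[[prot$kind]]
  if (is.null(block))
    stop("subject has no ", prot$kind, " data")
  value0 <- function(ch) {
    s <- block[[ch]]
    if (is.null(s)) stop("subject has no ", prot$kind, " ", ch, " series")
    if (prot$kind == "MT") {
      i <- match(0, s$time)
      if (is.na(i)) stop("no ", ch, " sample at t = 0 in MT data")
      s$value[i]
    } else {
      keep <- s$time >= 0 & s$time < 10
      if (!any(keep))
        stop("no ", ch, " samples in [0, 10) min of FSIGT data")
      mean(s$value[keep])
    }
  }
  state <- c(X = 0)
  if ("glucose" %in% channels) state <- c(G = value0("glucose"), state)
  if ("ffa" %in% channels) state <- c(state, F = value0("ffa"))
  state
}

## encode optional Ra objects into the 9-double block shared with C
ra_parms_block <- function(ra_glucose, ra_ffa) {
  block <- numeric(9)
  if (!is.null(ra_glucose)) {
    if (inherits(ra_glucose, "ra_type1"))
      block[1:4] <- c(1, ra_glucose$Delta, ra_glucose$m, ra_glucose$sigma)
    else if (inherits(ra_glucose, "ra_type2"))
      block[1:3] <- c(2, ra_glucose$phi, ra_glucose$tau)
    else stop("'ra_glucose' must be an ffamm_ra object")
  }
  if (!is.null(ra_ffa)) {
    if (!inherits(ra_ffa, "ra_type1"))
      stop("'ra_ffa' must be a Type I (log-normal-like) ffamm_ra object")
    block[5:9] <- c(1, ra_ffa$Delta, ra_ffa$m, ra_ffa$sigma, ra_ffa$t0)
  }
  block
}

#' Simulate a model over a protocol
#'
#' Integrates the chosen model variant with an adaptive stiff-capable
#' solver (`deSolve::lsoda`, relative tolerance `1e-8`) and reports the
#' solution on a 1-min grid spanning the protocol's fitting window (or
#' on user-supplied output times).  Measured insulin is interpolated
#' linearly between samples and clamped outside the sampled window.
#'
#' Rate-of-appearance terms apply to the meal test only: if a
#' `combination` is supplied, `ra_glucose` / `ra_ffa` are switched off
#' unless the combination activates them for the given protocol, and
#' they are always off for the IM-FSIGT.
#'
#' @param params model parameter object ([mod1_params()] etc.).
#' @param prot a protocol from [protocol()] (optional when `times`
#'   is given).
#' @param insulin measured insulin series (model input).
#' @param state0 named initial state (`c(G=,X=,F=)`; `c(F=)` for MOD 3),
#'   e.g. from [initial_conditions()].
#' @param ra_glucose,ra_ffa optional `ffamm_ra` meal appearance terms.
#' @param combination optional combination object from [combination()]
#'   used to gate the Ra terms.
#' @param times output time grid; default `seq(fit_window[1],
#'   fit_window[2], by = 1)`.
#' @param engine `"compiled"` (C right-hand sides, default) or `"R"`
#'   (reference implementation via [rhs_mod1()] and friends; slower,
#'   used for cross-checks).
#' @param rtol,atol solver tolerances.
#' @return a `data.frame` of class `ffamm_trajectory` with columns
#'   `time`, `G`, `X`, `F` (`time`, `F` for MOD 3).
#' @export
simulate_model <- function(params, prot = NULL, insulin, state0,
                           ra_glucose = NULL, ra_ffa = NULL,
                           combination = NULL, times = NULL,
                           engine = c("compiled", "R"),
                           rtol = 1e-8, atol = 1e-8) {
  engine <- match.arg(engine)
  model <- model_id(params)
  if (is.null(times)) {
    if (is.null(prot)) stop("either 'prot' or 'times' is required")
    times <- seq(prot$fit_window[1], prot$fit_window[2], by = 1)
  }
  if (!is.null(combination)) {
    act <- active_ra(combination, if (is.null(prot)) "MT" else prot$kind)
    if (!act["glucose"]) ra_glucose <- NULL
    if (!act["ffa"]) ra_ffa <- NULL
  } else if (!is.null(prot) && prot$kind == "FSIGT") {
    ra_glucose <- NULL
    ra_ffa <- NULL
  }
  insulin <- as_series(insulin, "insulin")
  if (engine == "compiled") {
    out <- simulate_compiled(model, params, insulin, state0,
                             ra_glucose, ra_ffa, times, rtol, atol)
  } else {
    out <- simulate_r(model, params, insulin, state0,
                      ra_glucose, ra_ffa, times, rtol, atol)
  }
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("integration failed (istate = ", istate[1], ") for model ",
         model)
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  if (anyNA(df) || any(!is.finite(as.matrix(df))))
    stop("integration produced non-finite values for model ", model)
  class(df) <- c("ffamm_trajectory", "data.frame")
  attr(df, "model") <- model
  df
}

simulate_compiled <- function(model, params, insulin, state0,
                              ra_glucose, ra_ffa, times, rtol, atol) {
  rb <- ra_parms_block(ra_glucose, ra_ffa)
  fctl <- list(method = "linear", rule = 2, f = 0, ties = "ordered")
  if (model == "MOD1") {
    parms <- c(params$S_G, params$G_b, params$S_I, params$C_x,
               params$I_bx, params$l_0, params$l_2, params$X_2,
               params$A_lipo, params$C_f, params$K_Cl, params$A_Cl, rb)
    deSolve::lsoda(y = state0[c("G", "X", "F")], times = times,
                   func = "ffamm_derivs_mod1", parms = parms,
                   dllname = "ffamm", initfunc = "ffamm_init_mod1",
                   initforc = "ffamm_forc_mod1",
                   forcings = list(cbind(insulin$time, insulin$value)),
                   fcontrol = fctl, rtol = rtol, atol = atol)
  } else if (model == "MOD2") {
    parms <- c(params$S_G, params$G_b, params$S_I, params$C_x,
               params$I_bx, params$l_0, params$l_2, params$X_2,
               params$A_l, params$C_f0, rb)
    deSolve::lsoda(y = state0[c("G", "X", "F")], times = times,
                   func = "ffamm_derivs_mod2", parms = parms,
                   dllname = "ffamm", initfunc = "ffamm_init_mod2",
                   initforc = "ffamm_forc_mod2",
                   forcings = list(cbind(insulin$time, insulin$value)),
                   fcontrol = fctl, rtol = rtol, atol = atol)
  } else {
    parms <- c(params$V_m_Lip, params$K_Lip, params$h_lip, params$k_Rem,
               params$V_m_Rem, params$K_Rem, params$h_Rem, 0, 0, rb)
    # delayed insulin realised by shifting the forcing time axis
    flip <- cbind(insulin$time + params$t_DelayLip, insulin$value)
    frem <- cbind(insulin$time + params$t_DelayRem, insulin$value)
    deSolve::lsoda(y = state0["F"], times = times,
                   func = "ffamm_derivs_mod3", parms = parms,
                   dllname = "ffamm", initfunc = "ffamm_init_mod3",
                   initforc = "ffamm_forc_mod3",
                   forcings = list(flip, frem),
                   fcontrol = fctl, rtol = rtol, atol = atol)
  }
}

## reference R-side integration through the exported rhs functions
simulate_r <- function(model, params, insulin, state0,
                       ra_glucose, ra_ffa, times, rtol, atol) {
  raG <- if (is.null(ra_glucose)) NULL else ra_fun(ra_glucose)
  raF <- if (is.null(ra_ffa)) NULL else ra_fun(ra_ffa)
  func <- switch(
    model,
    MOD1 = function(t, y, p)
      list(rhs_mod1(t, y, params, insulin, raG, raF)),
    MOD2 = function(t, y, p)
      list(rhs_mod2(t, y, params, insulin, raG, raF)),
    MOD3 = function(t, y, p)
      list(rhs_mod3(t, y, params, insulin, raF))
  )
  y0 <- if (model == "MOD3") state0["F"] else state0[c("G", "X", "F")]
  deSolve::lsoda(y = y0, times = times, func = func, parms = NULL,
                 rtol = rtol, atol = atol)
}
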