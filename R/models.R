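## Model parameter containers and right-hand sides.
##
## All three variants take measured plasma insulin as input.  MOD 1 and
## MOD 2 share the classic minimal-model glucose equation and a remote
## insulin-action compartment X; they differ in FFA clearance (insulin-
## stimulated for MOD 1, constant for MOD 2).  MOD 3 models FFA only and
## applies delayed plasma insulin directly to lipolysis and clearance.

check_nonneg <- function(p, names) {
  for (nm in names) {
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (v < 0) stop("parameter '", nm, "' must be non-negative")
  }
}

#' MOD 1 parameters: insulin-action model with insulin-stimulated FFA clearance
#'
#' Glucose follows the minimal model
#' \eqn{dG/dt = S_G G_b - (S_G + S_I X) G} driven by the remote insulin
#' action \eqn{dX/dt = C_x (I(t) - X - I_{bx})}.  FFA dynamics combine
#' Hill-suppressed lipolysis \eqn{l_0 + l_2/(1+(X/X_2)^{A_{lipo}})} with
#' an insulin-stimulated clearance
#' \eqn{C_f [1 + (X/K_{Cl})^{A_{Cl}} / (1 + (X/K_{Cl})^{A_{Cl}})] F},
#' so the clearance coefficient rises from \eqn{C_f} at basal action to
#' at most \eqn{2 C_f} at saturating action.
#'
#' @param S_G glucose effectiveness (1/min).
#' @param G_b target (basal) glucose (mg/dL).
#' @param S_I insulin sensitivity index (1/min per uU/mL).
#' @param C_x insulin-action rate constant (1/min).
#' @param I_bx action-threshold insulin (uU/mL); a fitted parameter, not
#'   necessarily equal to measured basal insulin.
#' @param l_0 basal (non-suppressible) lipolysis (mmol/L/min).
#' @param l_2 suppressible lipolysis (mmol/L/min).
#' @param X_2 insulin-action level at half-maximal lipolysis inhibition
#'   (uU/mL).
#' @param C_f FFA clearance coefficient (1/min).
#' @param K_Cl insulin-action level at half-maximal clearance activation
#'   (uU/mL).
#' @param A_lipo,A_Cl Hill exponents of the lipolysis and clearance terms;
#'   fixed at 2 by convention (model output is insensitive to them).
#' @return an object of class `c("mod1_params", "ffamm_params")`.
#' @export
mod1_params <- function(S_G, G_b, S_I, C_x, I_bx, l_0, l_2, X_2,
                        C_f, K_Cl, A_lipo = 2, A_Cl = 2) {
  p <- list(S_G = S_G, G_b = G_b, S_I = S_I, C_x = C_x, I_bx = I_bx,
            l_0 = l_0, l_2 = l_2, X_2 = X_2, A_lipo = A_lipo,
            C_f = C_f, K_Cl = K_Cl, A_Cl = A_Cl)
  check_nonneg(p, names(p))
  if ((p$l_2 > 0 || p$C_f > 0) && (p$X_2 <= 0 || p$K_Cl <= 0))
    stop("X_2 and K_Cl must be positive when l_2 > 0 or C_f > 0")
  structure(p, class = c("mod1_params", "ffamm_params"), model = "MOD1")
}

#' MOD 2 parameters: insulin-action model with constant FFA clearance
#'
#' Shares the glucose and insulin-action equations of [mod1_params()];
#' FFA clearance is the constant-rate term \eqn{C_{f0} F}, and the
#' lipolysis Hill exponent `A_l` is a free (fitted) parameter.
#'
#' @inheritParams mod1_params
#' @param A_l lipolysis Hill exponent (free).
#' @param C_f0 constant FFA clearance rate (1/min).
#' @return an object of class `c("mod2_params", "ffamm_params")`.
#' @export
mod2_params <- function(S_G, G_b, S_I, C_x, I_bx, l_0, l_2, X_2,
                        A_l, C_f0) {
  p <- list(S_G = S_G, G_b = G_b, S_I = S_I, C_x = C_x, I_bx = I_bx,
            l_0 = l_0, l_2 = l_2, X_2 = X_2, A_l = A_l, C_f0 = C_f0)
  check_nonneg(p, names(p))
  if (p$A_l <= 0) stop("A_l must be positive")
  if (p$l_2 > 0 && p$X_2 <= 0)
    stop("X_2 must be positive when l_2 > 0")
  structure(p, class = c("mod2_params", "ffamm_params"), model = "MOD2")
}

#' MOD 3 parameters: FFA-only model with delayed direct insulin action
#'
#' Plasma FFA is the only state.  Lipolysis is suppressed by delayed
#' plasma insulin, \eqn{V_m^{Lip} / (1 + (I(t - t_{DelayLip})/K_{Lip})^{h_{lip}})},
#' and removal combines an insulin-independent rate with a saturating
#' insulin-stimulated component,
#' \eqn{[k_{Rem} + V_m^{Rem} I_d^{h_{Rem}} / (K_{Rem}^{h_{Rem}} + I_d^{h_{Rem}})] F}
#' with \eqn{I_d = I(t - t_{DelayRem})}.
#'
#' @param V_m_Lip maximal lipolysis (mmol/L/min).
#' @param t_DelayLip insulin delay for lipolysis (min).
#' @param K_Lip insulin concentration at half-maximal lipolysis
#'   inhibition (uU/mL).
#' @param h_lip lipolysis Hill exponent.
#' @param k_Rem insulin-independent clearance rate (1/min).
#' @param V_m_Rem maximal insulin-stimulated clearance rate (1/min).
#' @param t_DelayRem insulin delay for clearance (min).
#' @param K_Rem insulin concentration at half-maximal clearance
#'   activation (uU/mL).
#' @param h_Rem clearance Hill exponent.
#' @return an object of class `c("mod3_params", "ffamm_params")`.
#' @export
mod3_params <- function(V_m_Lip, t_DelayLip, K_Lip, h_lip,
                        k_Rem, V_m_Rem, t_DelayRem, K_Rem, h_Rem) {
  p <- list(V_m_Lip = V_m_Lip, t_DelayLip = t_DelayLip, K_Lip = K_Lip,
            h_lip = h_lip, k_Rem = k_Rem, V_m_Rem = V_m_Rem,
            t_DelayRem = t_DelayRem, K_Rem = K_Rem, h_Rem = h_Rem)
  check_nonneg(p, names(p))
  if (p$K_Lip <= 0 && p$h_lip > 0)
    stop("K_Lip must be positive when h_lip > 0")
  if (p$K_Rem <= 0 && p$h_Rem > 0 && p$V_m_Rem > 0)
    stop("K_Rem must be positive when the insulin-stimulated clearance is active")
  structure(p, class = c("mod3_params", "ffamm_params"), model = "MOD3")
}

model_id <- function(params) attr(params, "model")

#' @export
print.ffamm_params <- function(x, ...) {
  cat(model_id(x), "parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Interpolated insulin input
#'
#' The models use measured plasma insulin as an external input.  Between
#' samples the record is linearly interpolated; outside the sampled
#' window it is clamped to the first/last sample value, so delayed
#' lookups before the record starts are well defined.
#'
#' @param t query time(s) (min).
#' @param insulin insulin series ([sampled_series()]) with at least two
#'   samples.
#' @param delay non-negative lookup delay (min): the value returned is
#'   `I(t - delay)`.
#' @return interpolated insulin concentration(s) (uU/mL).
#' @export
insulin_input <- function(t, insulin, delay = 0) {
  insulin_fun(insulin, delay)(t)
}

## closure version used in hot loops
insulin_fun <- function(insulin, delay = 0) {
  insulin <- as_series(insulin, "insulin")
  if (nrow(insulin) < 2L)
    stop("insulin series needs at least two samples")
  if (length(delay) != 1L || !is.finite(delay) || delay < 0)
    stop("'delay' must be a single non-negative number")
  f <- approxfun(insulin$time, insulin$value, rule = 2)
  function(t) f(t - delay)
}

## evaluate an optional Ra function (NULL contributes 0)
eval_ra <- function(ra, t) {
  if (is.null(ra)) return(0)
  if (inherits(ra, "ffamm_ra")) return(ra_eval(ra, t))
  ra(t)
}

## Hill terms clamp their argument at 0: adaptive solvers may probe
## slightly negative X, and non-integer exponents would go complex.
hill_up <- function(x, K, A) {
  h <- (max(x, 0) / K)^A
  h / (1 + h)
}
hill_down <- function(x, K, A) 1 / (1 + (max(x, 0) / K)^A)

#' Model right-hand sides
#'
#' Evaluate the time derivatives of one model variant at a given state.
#' These are the pure equations used by [simulate_model()]; exported for
#' testing and for inspection of individual flux terms.  `ra_glucose` /
#' `ra_ffa` are optional meal rate-of-appearance terms (an `ffamm_ra`
#' object or a function of time); when absent they contribute zero, as
#' in the IM-FSIGT protocol.
#'
#' @param t time (min).
#' @param state named numeric vector `c(G=,X=,F=)` (for MOD 3 a single
#'   value `F`).
#' @param params a parameter object of the matching model.
#' @param insulin insulin series used as model input.
#' @param ra_glucose,ra_ffa optional rate-of-appearance terms.
#' @return named vector of derivatives (per min).
#' @export
rhs_mod1 <- function(t, state, params, insulin, ra_glucose = NULL,
                     ra_ffa = NULL) {
  stopifnot(inherits(params, "mod1_params"))
  G <- state[["G"]]; X <- state[["X"]]; F <- state[["F"]]
  I <- insulin_input(t, insulin)
  dG <- params$S_G * params$G_b - (params$S_G + params$S_I * X) * G +
    eval_ra(ra_glucose, t)
  dX <- params$C_x * (I - X - params$I_bx)
  dF <- params$l_0 + params$l_2 * hill_down(X, params$X_2, params$A_lipo) -
    params$C_f * (1 + hill_up(X, params$K_Cl, params$A_Cl)) * F +
    eval_ra(ra_ffa, t)
  c(G = dG, X = dX, F = dF)
}

#' @rdname rhs_mod1
#' @export
rhs_mod2 <- function(t, state, params, insulin, ra_glucose = NULL,
                     ra_ffa = NULL) {
  stopifnot(inherits(params, "mod2_params"))
  G <- state[["G"]]; X <- state[["X"]]; F <- state[["F"]]
  I <- insulin_input(t, insulin)
  dG <- params$S_G * params$G_b - (params$S_G + params$S_I * X) * G +
    eval_ra(ra_glucose, t)
  dX <- params$C_x * (I - X - params$I_bx)
  dF <- params$l_0 + params$l_2 * hill_down(X, params$X_2, params$A_l) -
    params$C_f0 * F + eval_ra(ra_ffa, t)
  c(G = dG, X = dX, F = dF)
}

#' @rdname rhs_mod1
#' @export
rhs_mod3 <- function(t, state, params, insulin, ra_ffa = NULL) {
  stopifnot(inherits(params, "mod3_params"))
  F <- if (is.null(names(state))) state[[1L]] else state[["F"]]
  Ilip <- insulin_input(t, insulin, delay = params$t_DelayLip)
  Irem <- insulin_input(t, insulin, delay = params$t_DelayRem)
  lip <- params$V_m_Lip * hill_down(Ilip, params$K_Lip, params$h_lip)
  clr <- params$k_Rem +
    params$V_m_Rem * hill_up(Irem, params$K_Rem, params$h_Rem)
  c(F = lip - clr * F + eval_ra(ra_ffa, t))
}

#' Basal steady state of a model
#'
#' Returns the fixed point reached when insulin action vanishes and all
#' rate-of-appearance terms are zero: glucose rests at `G_b`, insulin
#' action at 0, and FFA at the balance of basal lipolysis and clearance
#' (`(l_0 + l_2)/C_f` for MOD 1, `(l_0 + l_2)/C_f0` for MOD 2).  For
#' MOD 3, which has no action compartment, the steady state is computed
#' at a constant basal insulin level (default 0, giving
#' `V_m_Lip / k_Rem`).
#'
#' @param params a model parameter object.
#' @param insulin_basal constant basal insulin (uU/mL), used by MOD 3.
#' @return named state vector at the fixed point.
#' @export
steady_state <- function(params, insulin_basal = 0) {
  UseMethod("steady_state")
}

#' @export
steady_state.mod1_params <- function(params, insulin_basal = 0) {
  if (params$C_f <= 0) stop("no steady state: C_f must be positive")
  c(G = params$G_b, X = 0, F = (params$l_0 + params$l_2) / params$C_f)
}

#' @export
steady_state.mod2_params <- function(params, insulin_basal = 0) {
  if (params$C_f0 <= 0) stop("no steady state: C_f0 must be positive")
  c(G = params$G_b, X = 0, F = (params$l_0 + params$l_2) / params$C_f0)
}

#' @export
steady_state.mod3_params <- function(params, insulin_basal = 0) {
  lip <- params$V_m_Lip *
    hill_down(insulin_basal, params$K_Lip, params$h_lip)
  clr <- params$k_Rem +
    params$V_m_Rem * hill_up(insulin_basal, params$K_Rem, params$h_Rem)
  if (clr <= 0) stop("no steady state: total clearance rate is zero")
  c(F = lip / clr)
}
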