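## Synthetic subjects and reference parameter values.
##
## No subject-level data ship with the package, so validation runs on
## synthetic subjects: a deterministic insulin input emulating the
## protocol time courses drives the chosen model variant, glucose and
## FFA are sampled at the protocol times, and multiplicative noise
## emulates assay variability.  Generating parameters come from a
## registry of published group-mean values, so round-trip fitting of a
## synthetic subject checks the whole pipeline.

## ---- reference group means --------------------------------------------

ref_tables <- local({
  m1 <- function(aa, wh) list(AA = aa, white = wh)
  MOD1 <- list(
    C1 = m1(c(S_G = 0.014, G_b = 128.8, S_I = 4.1e-4, C_x = 0.042,
              I_bx = 5.1, l_0 = 0.008, l_2 = 0.14, X_2 = 14.1,
              C_f = 0.092, K_Cl = 25.3),
            c(S_G = 0.012, G_b = 138.1, S_I = 6.3e-4, C_x = 0.053,
              I_bx = 5.4, l_0 = 0.017, l_2 = 0.12, X_2 = 14.1,
              C_f = 0.13, K_Cl = 15.3)),
    C2 = m1(c(S_G = 0.0046, G_b = 186.5, S_I = 3.1e-4, C_x = 0.076,
              I_bx = 3.02, l_0 = 0.0026, l_2 = 0.12, X_2 = 12.7,
              C_f = 0.035, K_Cl = 23.32, m_G = 118.4, sigma_G = 0.67,
              Delta_G = 65.9, sigma_F = 0.61, Delta_F = 0.32),
            c(S_G = 0.0064, G_b = 162.29, S_I = 5.1e-4, C_x = 0.069,
              I_bx = 4.54, l_0 = 0.003, l_2 = 0.048, X_2 = 14.1,
              C_f = 0.029, K_Cl = 12.1, m_G = 101.9, sigma_G = 1.1,
              Delta_G = 63.2, sigma_F = 0.45, Delta_F = 0.36)),
    C3 = m1(c(S_G = 5.6e-3, G_b = 136.4, S_I = 3.2e-4, C_x = 0.12,
              I_bx = 4.6, l_0 = 0.006, l_2 = 0.12, X_2 = 12.7,
              C_f = 0.047, K_Cl = 21.7, m_G = 124.9, sigma_G = 0.66,
              Delta_G = 67.9),
            c(S_G = 6.3e-3, G_b = 156.9, S_I = 4.9e-4, C_x = 0.07,
              I_bx = 4.1, l_0 = 0.0017, l_2 = 0.052, X_2 = 13.6,
              C_f = 0.031, K_Cl = 7.9, m_G = 107.1, sigma_G = 0.90,
              Delta_G = 65.5)),
    C4 = m1(c(S_G = 0.012, G_b = 130.8, S_I = 0.0077, C_x = 0.046,
              I_bx = 5.2, l_0 = 0.0086, l_2 = 0.089, X_2 = 13.1,
              C_f = 0.063, K_Cl = 18.6, phi_G = 68.3, tau_G = 68.4),
            c(S_G = 0.0087, G_b = 142.8, S_I = 5.5e-4, C_x = 0.091,
              I_bx = 5.5, l_0 = 7.4e-4, l_2 = 0.049, X_2 = 12.6,
              C_f = 0.029, K_Cl = 6.1, phi_G = 58.1, tau_G = 33.1))
  )
  MOD2 <- list(
    C1 = m1(c(S_G = 0.015, G_b = 129.5, S_I = 4.1e-4, C_x = 0.41,
              I_bx = 5.11, l_0 = 0.0095, l_2 = 0.98, X_2 = 11.7,
              A_l = 2.19, C_f0 = 0.15),
            c(S_G = 0.014, G_b = 165.9, S_I = 5.9e-4, C_x = 0.042,
              I_bx = 3.24, l_0 = 0.0036, l_2 = 0.15, X_2 = 12.8,
              A_l = 2.57, C_f0 = 0.19)),
    C2 = m1(c(S_G = 0.0061, G_b = 189.7, S_I = 3.6e-4, C_x = 0.072,
              I_bx = 5.63, l_0 = 0.033, l_2 = 0.24, X_2 = 12.12,
              A_l = 2.13, C_f0 = 0.25, m_G = 122.31, sigma_G = 0.66,
              Delta_G = 62.7, sigma_F = 0.60, Delta_F = 0.53),
            c(S_G = 0.0081, G_b = 170.54, S_I = 5.9e-4, C_x = 0.057,
              I_bx = 3.47, l_0 = 0.0092, l_2 = 0.17, X_2 = 12.9,
              A_l = 2.45, C_f0 = 0.17, m_G = 100.9, sigma_G = 0.93,
              Delta_G = 59.6, sigma_F = 0.28, Delta_F = 0.68)),
    C3 = m1(c(S_G = 6.5e-3, G_b = 179.3, S_I = 3.9e-4, C_x = 0.11,
              I_bx = 7.4, l_0 = 0.033, l_2 = 0.23, X_2 = 13.4,
              A_l = 2.1, C_f0 = 0.23, m_G = 124.6, sigma_G = 0.71,
              Delta_G = 61.2),
            c(S_G = 7.2e-3, G_b = 170.5, S_I = 5.5e-4, C_x = 0.053,
              I_bx = 5.2, l_0 = 0.027, l_2 = 0.19, X_2 = 13.2,
              A_l = 2.4, C_f0 = 0.22, m_G = 99.4, sigma_G = 0.78,
              Delta_G = 59.3)),
    C4 = m1(c(S_G = 0.011, G_b = 119.9, S_I = 4e-4, C_x = 0.042,
              I_bx = 6.0, l_0 = 0.0038, l_2 = 0.13, X_2 = 15.6,
              A_l = 2.3, C_f0 = 0.092, phi_G = 77.2, tau_G = 82.9),
            c(S_G = 8.9e-3, G_b = 194.2, S_I = 5.8e-4, C_x = 0.059,
              I_bx = 4.5, l_0 = 0.023, l_2 = 0.14, X_2 = 13.1,
              A_l = 2.4, C_f0 = 0.13, phi_G = 83.7, tau_G = 64.2))
  )
  MOD3 <- list(
    C1 = m1(c(V_m_Lip = 0.54, t_DelayLip = 26.9, K_Lip = 25.2,
              h_lip = 4.1, k_Rem = 0.33, V_m_Rem = 0.11,
              t_DelayRem = 12.0, K_Rem = 47.4, h_Rem = 5.3),
            c(V_m_Lip = 3.2, t_DelayLip = 36.4, K_Lip = 10.2,
              h_lip = 2.3, k_Rem = 0.67, V_m_Rem = 0.44,
              t_DelayRem = 15.6, K_Rem = 42.6, h_Rem = 7.8)),
    C2 = m1(c(V_m_Lip = 2.02, t_DelayLip = 24.9, K_Lip = 10.4,
              h_lip = 2, k_Rem = 0.16, V_m_Rem = 0.25,
              t_DelayRem = 12.6, K_Rem = 38.4, h_Rem = 6.38,
              sigma_F = 0.47, Delta_F = 0.24),
            c(V_m_Lip = 2.35, t_DelayLip = 35.7, K_Lip = 10.5,
              h_lip = 1.8, k_Rem = 0.43, V_m_Rem = 0.48,
              t_DelayRem = 14.2, K_Rem = 45.4, h_Rem = 6.72,
              sigma_F = 0.55, Delta_F = 0.3))
  )
  list(MOD1 = MOD1, MOD2 = MOD2, MOD3 = MOD3)
})

#' Published group-mean parameter values
#'
#' Reference means (per model, combination and ethnic group) used for
#' fitting bounds and default optimisation starts.  The single-protocol
#' combinations map onto the reference columns of the corresponding
#' joint combination (S1 uses C1 means, S2 uses C3, S3 uses C4).
#'
#' @param model `"MOD1"`, `"MOD2"` or `"MOD3"`.
#' @param combination combination id (`"C1"` ... `"S3"`).
#' @param group `"AA"` or `"white"`.
#' @return named numeric vector of group means.
#' @export
reference_means <- function(model, combination, group = c("AA", "white")) {
  group <- match.arg(group)
  combination <- switch(combination, S1 = "C1", S2 = "C3", S3 = "C4",
                        combination)
  tab <- ref_tables[[model]]
  if (is.null(tab)) stop("unknown model '", model, "'")
  if (is.null(tab[[combination]]))
    stop("no reference means for ", model, " combination ", combination)
  tab[[combination]][[group]]
}

## ---- fixtures ---------------------------------------------------------

#' Named parameter fixtures
#'
#' Complete generating parameter sets used by the synthetic-subject
#' generator, taken from the group-mean registry:
#' \describe{
#'   \item{`"AA-C3"`}{MOD 1 under Combination 3 (Type I glucose Ra),
#'     AA group means.}
#'   \item{`"WH-C4"`}{MOD 1 under Combination 4 (Type II glucose Ra),
#'     white group means.}
#' }
#'
#' @param name fixture name.
#' @return a list with elements `name`, `model`, `combination`, `group`,
#'   `params` (full parameter object), `ra_glucose`, `ra_ffa` and
#'   `theta` (the named free-parameter vector of the generating values).
#' @export
fixture <- function(name) {
  known <- list(
    `AA-C3` = list(model = "MOD1", combination = "C3", group = "AA"),
    `WH-C4` = list(model = "MOD1", combination = "C4", group = "white")
  )
  info <- known[[name]]
  if (is.null(info))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(known), collapse = ", "))
  ref <- reference_means(info$model, info$combination, info$group)
  combo <- combination(info$combination)
  free <- free_param_names(info$model, combo)
  theta <- ref[free]
  objects <- build_objects(info$model, theta, combo)
  c(list(name = name), info,
    list(params = objects$params, ra_glucose = objects$ra_glucose,
         ra_ffa = objects$ra_ffa, theta = theta))
}

#' @rdname fixture
#' @export
fixture_names <- function() c("AA-C3", "WH-C4")

## ---- insulin input shapes ---------------------------------------------

#' Synthetic insulin input shape
#'
#' Parameterises the deterministic insulin time courses used by
#' [synth_insulin()].  The IM-FSIGT shape has a basal level, an
#' endogenous first-phase peak just after the t = 0 glucose bolus, and
#' a larger exogenous spike after the 20-min insulin bolus; each pulse
#' is `height * rate * e * dt * exp(-rate * dt)`, peaking (at the given
#' height) `1/rate` minutes after its onset.  The meal shape is a
#' single smooth excursion `peak * (t/ttp)^s * exp(s (1 - t/ttp))`
#' peaking at `ttp` and relaxing toward basal well before 360 min.
#' Defaults give an FSIGT peak about 10x basal, an exogenous spike
#' about 25x basal, and a meal peak about 5x basal.
#'
#' @param basal basal insulin (uU/mL).
#' @param fsigt_peak1,fsigt_rate1 height (above basal) and decay rate
#'   (1/min) of the endogenous first-phase peak at t = 0.
#' @param fsigt_peak2,fsigt_rate2 height and decay rate of the
#'   exogenous spike at t = 20 min.
#' @param mt_peak,mt_time_to_peak,mt_shape height above basal, time of
#'   the meal insulin peak (min), and shape exponent.
#' @return a list of class `ffamm_insulin_shape`.
#' @export
insulin_shape <- function(basal = 5, fsigt_peak1 = 50, fsigt_rate1 = 0.35,
                          fsigt_peak2 = 120, fsigt_rate2 = 0.12,
                          mt_peak = 20, mt_time_to_peak = 40,
                          mt_shape = 2) {
  vals <- c(basal, fsigt_peak1, fsigt_rate1, fsigt_peak2, fsigt_rate2,
            mt_peak, mt_time_to_peak, mt_shape)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("insulin shape parameters must be finite and non-negative")
  structure(list(basal = basal, fsigt_peak1 = fsigt_peak1,
                 fsigt_rate1 = fsigt_rate1, fsigt_peak2 = fsigt_peak2,
                 fsigt_rate2 = fsigt_rate2, mt_peak = mt_peak,
                 mt_time_to_peak = mt_time_to_peak, mt_shape = mt_shape),
            class = "ffamm_insulin_shape")
}

pulse_shape <- function(t, onset, rate) {
  dt <- t - onset
  out <- numeric(length(t))
  pos <- dt > 0 & rate > 0
  out[pos] <- rate * exp(1) * dt[pos] * exp(-rate * dt[pos])
  out
}

#' Deterministic synthetic insulin series
#'
#' Evaluates an [insulin_shape()] at the sample times of a protocol.
#' Values at the pre-stimulus times (-10, -1 min) equal the basal
#' level.
#'
#' @param prot a protocol from [protocol()].
#' @param shape an [insulin_shape()].
#' @return a [sampled_series()] of insulin (uU/mL).
#' @export
synth_insulin <- function(prot, shape = insulin_shape()) {
  stopifnot(inherits(prot, "ffamm_protocol"),
            inherits(shape, "ffamm_insulin_shape"))
  t <- prot$sample_times
  if (prot$kind == "FSIGT") {
    v <- shape$basal +
      shape$fsigt_peak1 * pulse_shape(t, 0, shape$fsigt_rate1) +
      shape$fsigt_peak2 * pulse_shape(t, 20, shape$fsigt_rate2)
  } else {
    ttp <- shape$mt_time_to_peak
    s <- shape$mt_shape
    v <- shape$basal + ifelse(
      t > 0 & ttp > 0,
      shape$mt_peak * (t / ttp)^s * exp(s * (1 - t / ttp)), 0)
  }
  sampled_series(t, v)
}

## ---- synthetic subjects -----------------------------------------------

#' Generate a protocol-faithful synthetic subject
#'
#' Simulates the fixture's model variant under its combination over the
#' fixture's protocols, driven by a deterministic synthetic insulin
#' input, samples glucose and FFA at the protocol times, and applies
#' independent multiplicative Gaussian noise with coefficient of
#' variation `noise_cv` to the sampled values (never inside the ODE
#' integration).  Insulin, being the model input, is left noiseless.
#'
#' The IM-FSIGT trajectory is integrated over the fitting window
#' \[10, 180\] min from `G(10) = g0_fsigt`, `X(10) = 0` and FFA at its
#' basal steady state; the 0-8 min samples are reported at the initial
#' values (a post-bolus mixing plateau), so the protocol's
#' initial-value convention reproduces the generating state exactly,
#' and the pre-bolus samples (-10, -1 min) sit at basal.  The meal-test
#' trajectory starts from basal glucose `G_b` and basal FFA at t = 0.
#'
#' When `noise_cv > 0` the subject's `sigma2` entries are set to the
#' true per-channel mean noise variances; with `noise_cv = 0` they are
#' unit, so that noiseless round-trip fits use unweighted residuals.
#'
#' @param fix a fixture name (see [fixture()]) or fixture object.
#' @param shape an [insulin_shape()].
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (0 for noiseless data).
#' @param seed integer seed making the noise reproducible.
#' @param g0_fsigt post-bolus initial glucose for the IM-FSIGT (mg/dL).
#' @param engine,rtol,atol solver options (see [simulate_model()]).
#' @return an `ffamm_subject` with attribute `"truth"` holding the
#'   generating fixture.
#' @export
synth_subject <- function(fix, shape = insulin_shape(), noise_cv = 0,
                          seed = NULL, g0_fsigt = 250,
                          engine = "compiled", rtol = 1e-8, atol = 1e-8) {
  if (is.character(fix)) fix <- fixture(fix)
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  combo <- combination(fix$combination)
  channels <- model_channels(fix$model)
  basal <- steady_state(fix$params)
  if (!is.null(seed)) set.seed(seed)

  blocks <- list()
  sigma2 <- list()
  for (p in combo$protocols) {
    prot <- protocol(p)
    insulin <- synth_insulin(prot, shape)
    if (p == "FSIGT") {
      state0 <- c(G = g0_fsigt, X = 0, F = unname(basal["F"]))
      times <- fit_times(prot)   # integration starts at t = 10
    } else {
      state0 <- c(G = unname(basal["G"]), X = 0, F = unname(basal["F"]))
      times <- prot$sample_times
    }
    if (fix$model == "MOD3") state0 <- state0["F"]
    act <- active_ra(combo, p)
    sim <- simulate_model(fix$params, prot = prot, insulin = insulin,
                          state0 = state0,
                          ra_glucose = if (act["glucose"]) fix$ra_glucose,
                          ra_ffa = if (act["ffa"]) fix$ra_ffa,
                          times = times, engine = engine,
                          rtol = rtol, atol = atol)
    grab <- function(col) sim[[col]][match(prot$sample_times, sim$time)]
    clean <- list()
    if ("glucose" %in% channels) {
      g <- grab("G")
      if (p == "FSIGT") {
        g[prot$sample_times < 0] <- fix$params$G_b
        g[prot$sample_times >= 0 & prot$sample_times < 10] <- g0_fsigt
      }
      clean$glucose <- g
    }
    f <- grab("F")
    if (p == "FSIGT") f[prot$sample_times < 10] <- unname(basal["F"])
    clean$ffa <- f

    noisy <- lapply(clean, function(y) {
      if (noise_cv == 0) y else y * (1 + noise_cv * rnorm(length(y)))
    })
    blocks[[p]] <- c(list(insulin = insulin),
                     lapply(noisy, function(v)
                       sampled_series(prot$sample_times, v)))
    sigma2[[p]] <- vapply(clean, function(y) {
      if (noise_cv == 0) 1 else mean((noise_cv * y)^2)
    }, numeric(1))
  }
  subj <- subject_data(fsigt = blocks$FSIGT, mt = blocks$MT,
                       sigma2 = sigma2)
  attr(subj, "truth") <- fix
  subj
}
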