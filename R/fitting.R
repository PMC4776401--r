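## Per-subject weighted least-squares estimation.
##
## The objective is the variance-weighted residual sum of squares
##   sum_p sum_m sum_t (y_data - y_model)^2 / sigma2[p, m]
## over the glucose and FFA channels (m) of each active protocol (p) at
## the protocol sample times inside the fitting window.  Insulin is the
## model input and never a residual channel; MOD 3 contributes FFA
## residuals only.  sigma2 is one scalar per (protocol, channel) pair,
## by default estimated from the raw data by rank-1 SSA smoothing.

#' Simulation combinations
#'
#' A combination selects which protocols are fitted jointly and which
#' meal rate-of-appearance terms are active in the meal test (Ra terms
#' never apply to the IM-FSIGT):
#' \describe{
#'   \item{C1}{FSIGT + MT, no Ra at all.}
#'   \item{C2}{FSIGT + MT, Type I glucose Ra and Type I FFA Ra.}
#'   \item{C3}{FSIGT + MT, Type I glucose Ra only.}
#'   \item{C4}{FSIGT + MT, Type II glucose Ra only.}
#'   \item{S1}{FSIGT only, no Ra.}
#'   \item{S2}{MT only, Type I glucose Ra.}
#'   \item{S3}{MT only, Type II glucose Ra.}
#' }
#'
#' @param id one of `"C1"`, `"C2"`, `"C3"`, `"C4"`, `"S1"`, `"S2"`, `"S3"`.
#' @return an object of class `ffamm_combination`.
#' @export
combination <- function(id) {
  if (inherits(id, "ffamm_combination")) return(id)
  reg <- list(
    C1 = list(protocols = c("FSIGT", "MT"), ra_glucose = "none",
              ra_ffa = "none"),
    C2 = list(protocols = c("FSIGT", "MT"), ra_glucose = "type1",
              ra_ffa = "type1"),
    C3 = list(protocols = c("FSIGT", "MT"), ra_glucose = "type1",
              ra_ffa = "none"),
    C4 = list(protocols = c("FSIGT", "MT"), ra_glucose = "type2",
              ra_ffa = "none"),
    S1 = list(protocols = "FSIGT", ra_glucose = "none", ra_ffa = "none"),
    S2 = list(protocols = "MT", ra_glucose = "type1", ra_ffa = "none"),
    S3 = list(protocols = "MT", ra_glucose = "type2", ra_ffa = "none")
  )
  if (!is.character(id) || length(id) != 1L || is.na(match(id, names(reg))))
    stop("unknown combination; use one of ",
         paste(names(reg), collapse = ", "))
  structure(c(list(id = id), reg[[id]]), class = "ffamm_combination")
}

## which Ra terms are active for a protocol under a combination
active_ra <- function(combo, protocol_kind) {
  if (protocol_kind != "MT")
    return(c(glucose = FALSE, ffa = FALSE))
  c(glucose = combo$ra_glucose != "none", ffa = combo$ra_ffa != "none")
}

## residual channels of a model
model_channels <- function(model) {
  if (model == "MOD3") "ffa" else c("glucose", "ffa")
}

## default fixed parameters (standard fixing conventions, togglable)
default_fixed <- function() list(A_lipo = 2, A_Cl = 2, m_F = 300, t_0F = 60)

## free parameter names for a model under a combination
free_param_names <- function(model, combo, fixed = default_fixed()) {
  combo <- combination(combo)
  base <- switch(
    model,
    MOD1 = {
      nm <- c("S_G", "G_b", "S_I", "C_x", "I_bx", "l_0", "l_2", "X_2",
              "C_f", "K_Cl")
      if (is.null(fixed$A_lipo)) nm <- c(nm, "A_lipo")
      if (is.null(fixed$A_Cl)) nm <- c(nm, "A_Cl")
      nm
    },
    MOD2 = c("S_G", "G_b", "S_I", "C_x", "I_bx", "l_0", "l_2", "X_2",
             "A_l", "C_f0"),
    MOD3 = c("V_m_Lip", "t_DelayLip", "K_Lip", "h_lip", "k_Rem",
             "V_m_Rem", "t_DelayRem", "K_Rem", "h_Rem"),
    stop("unknown model '", model, "'")
  )
  if (model != "MOD3") {
    if (combo$ra_glucose == "type1")
      base <- c(base, "Delta_G", "m_G", "sigma_G")
    if (combo$ra_glucose == "type2")
      base <- c(base, "phi_G", "tau_G")
  }
  if (combo$ra_ffa == "type1") {
    base <- c(base, "Delta_F", "sigma_F")
    if (is.null(fixed$m_F)) base <- c(base, "m_F")
    if (is.null(fixed$t_0F)) base <- c(base, "t_0F")
  }
  base
}

## assemble parameter and Ra objects from a named free-parameter vector
build_objects <- function(model, theta, combo, fixed = default_fixed()) {
  combo <- combination(combo)
  g <- function(nm, default = NULL) {
    if (nm %in% names(theta)) return(unname(theta[[nm]]))
    if (!is.null(fixed[[nm]])) return(fixed[[nm]])
    if (!is.null(default)) return(default)
    stop("parameter '", nm, "' neither free nor fixed")
  }
  params <- switch(
    model,
    MOD1 = mod1_params(S_G = g("S_G"), G_b = g("G_b"), S_I = g("S_I"),
                       C_x = g("C_x"), I_bx = g("I_bx"), l_0 = g("l_0"),
                       l_2 = g("l_2"), X_2 = g("X_2"), C_f = g("C_f"),
                       K_Cl = g("K_Cl"), A_lipo = g("A_lipo"),
                       A_Cl = g("A_Cl")),
    MOD2 = mod2_params(S_G = g("S_G"), G_b = g("G_b"), S_I = g("S_I"),
                       C_x = g("C_x"), I_bx = g("I_bx"), l_0 = g("l_0"),
                       l_2 = g("l_2"), X_2 = g("X_2"), A_l = g("A_l"),
                       C_f0 = g("C_f0")),
    MOD3 = mod3_params(V_m_Lip = g("V_m_Lip"),
                       t_DelayLip = g("t_DelayLip"), K_Lip = g("K_Lip"),
                       h_lip = g("h_lip"), k_Rem = g("k_Rem"),
                       V_m_Rem = g("V_m_Rem"),
                       t_DelayRem = g("t_DelayRem"), K_Rem = g("K_Rem"),
                       h_Rem = g("h_Rem"))
  )
  ra_g <- NULL
  if (model != "MOD3") {
    if (combo$ra_glucose == "type1")
      ra_g <- ra_type1_glucose(g("Delta_G"), g("m_G"), g("sigma_G"))
    if (combo$ra_glucose == "type2")
      ra_g <- ra_type2_glucose(g("phi_G"), g("tau_G"))
  }
  ra_f <- NULL
  if (combo$ra_ffa == "type1")
    ra_f <- ra_type1_ffa(g("Delta_F"), g("sigma_F"), m_F = g("m_F"),
                         t_0F = g("t_0F"))
  list(params = params, ra_glucose = ra_g, ra_ffa = ra_f)
}

## resolve the sigma2 weights for the active (protocol, channel) pairs
resolve_sigma2 <- function(subject, model, combo,
                           sigma2 = c("subject", "ssa", "unit")) {
  combo <- combination(combo)
  channels <- model_channels(model)
  if (is.list(sigma2)) return(sigma2)
  mode <- match.arg(sigma2)
  if (mode == "subject" && !is.null(subject$sigma2))
    return(subject$sigma2)
  out <- list()
  for (p in combo$protocols) {
    v <- numeric(0)
    for (ch in channels) {
      s <- subject[[p]][[ch]]
      if (is.null(s)) next
      v[ch] <- if (mode == "unit") 1 else estimate_variance(s)$sigma2
    }
    out[[p]] <- v
  }
  out
}

## weighted residual table for given model/Ra objects
residual_table <- function(objects, subject, combo, sigma2,
                           engine = "compiled", rtol = 1e-8,
                           atol = 1e-8) {
  combo <- combination(combo)
  model <- model_id(objects$params)
  channels <- model_channels(model)
  rows <- list()
  for (p in combo$protocols) {
    prot <- protocol(p)
    block <- subject[[p]]
    if (is.null(block))
      stop("combination ", combo$id, " requires ", p, " data")
    state0 <- initial_conditions(prot, subject, channels = channels)
    act <- active_ra(combo, p)
    tneed <- sort(unique(c(prot$fit_window[1], unlist(lapply(
      channels, function(ch) {
        s <- block[[ch]]
        if (is.null(s)) stop("subject lacks ", p, " ", ch, " series")
        s$time[s$time >= prot$fit_window[1] & s$time <= prot$fit_window[2]]
      })))))
    sim <- simulate_model(objects$params, prot = prot,
                          insulin = block$insulin, state0 = state0,
                          ra_glucose = if (act["glucose"]) objects$ra_glucose,
                          ra_ffa = if (act["ffa"]) objects$ra_ffa,
                          times = tneed, engine = engine,
                          rtol = rtol, atol = atol)
    for (ch in channels) {
      s <- block[[ch]]
      keep <- s$time >= prot$fit_window[1] & s$time <= prot$fit_window[2]
      tt <- s$time[keep]
      ymod <- sim[[if (ch == "glucose") "G" else "F"]][match(tt, sim$time)]
      s2 <- sigma2[[p]][[ch]]
      if (is.null(s2) || !is.finite(s2) || s2 <= 0)
        stop("missing or invalid sigma2 for ", p, " ", ch)
      rows[[paste(p, ch)]] <- data.frame(
        protocol = p, channel = ch, time = tt, data = s$value[keep],
        model = ymod, resid = s$value[keep] - ymod, sigma2 = s2)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Weighted fitting objective
#'
#' Evaluates the variance-weighted residual sum of squares of a model
#' against a subject's data under a given combination: the sum over
#' active protocols and channels of `(y_data - y_model)^2 / sigma2`,
#' at the sample times inside each protocol's fitting window.
#'
#' @param params model parameter object.
#' @param subject an `ffamm_subject`.
#' @param combo a combination id or object (see [combination()]).
#' @param sigma2 `"subject"` (use the subject's stored variances, if
#'   any, else SSA estimates), `"ssa"`, `"unit"`, or an explicit list
#'   like `list(FSIGT = c(glucose =, ffa =), MT = ...)`.
#' @param ra_glucose,ra_ffa optional `ffamm_ra` objects matching the
#'   combination.
#' @param ... solver options passed on (`engine`, `rtol`, `atol`).
#' @return the objective value (dimensionless); if the integration
#'   fails, a large finite penalty (`1e12`) with a warning.
#' @export
fit_objective <- function(params, subject, combo, sigma2 = "subject",
                          ra_glucose = NULL, ra_ffa = NULL, ...) {
  combo <- combination(combo)
  model <- model_id(params)
  s2 <- resolve_sigma2(subject, model, combo, sigma2)
  objects <- list(params = params, ra_glucose = ra_glucose,
                  ra_ffa = ra_ffa)
  tab <- tryCatch(
    residual_table(objects, subject, combo, s2, ...),
    error = function(e) {
      warning("integration failed in objective: ", conditionMessage(e))
      NULL
    })
  if (is.null(tab)) return(1e12)
  sum(tab$resid^2 / tab$sigma2)
}

## parameters whose value must stay strictly positive (they appear in
## denominators or logs); bounded below at a small fraction of the
## reference mean instead of exactly 0
strictly_positive <- c("X_2", "K_Cl", "m_G", "sigma_G", "tau_G",
                       "sigma_F", "K_Lip", "K_Rem", "m_F")

#' Default parameter bounds for fitting
#'
#' Lower bounds are zero (a small positive guard, `1e-3` of the
#' reference mean, for scale parameters that appear in denominators);
#' upper bounds are `multiplier` (default 5) times the group-mean
#' reference value for the model/combination, with insulin delays
#' additionally capped at 180 min.
#'
#' @param model `"MOD1"`, `"MOD2"` or `"MOD3"`.
#' @param combo combination id or object.
#' @param group reference group for the means, `"AA"` or `"white"`.
#' @param multiplier upper bound as a multiple of the reference mean.
#' @param fixed list of fixed parameters (see [fit_config()]).
#' @return list with named vectors `lower`, `upper` and `ref` (the
#'   reference means used).
#' @export
default_bounds <- function(model, combo, group = "AA", multiplier = 5,
                           fixed = default_fixed()) {
  combo <- combination(combo)
  free <- free_param_names(model, combo, fixed)
  ref <- reference_means(model, combo$id, group)
  miss <- setdiff(free, names(ref))
  if (length(miss))
    stop("no reference mean for parameter(s): ",
         paste(miss, collapse = ", "))
  ref <- ref[free]
  lower <- setNames(rep(0, length(free)), free)
  sp <- intersect(free, strictly_positive)
  lower[sp] <- 1e-3 * ref[sp]
  upper <- multiplier * ref
  delays <- intersect(free, c("t_DelayLip", "t_DelayRem"))
  upper[delays] <- pmin(upper[delays], 180)
  list(lower = lower, upper = upper, ref = ref)
}

#' Fitting configuration
#'
#' @param sigma2 weighting mode or explicit variances; see
#'   [fit_objective()].
#' @param group reference group used for bounds and default starts.
#' @param bounds_multiplier upper bound as a multiple of the reference
#'   means.
#' @param bounds optional explicit bounds (list with `lower`, `upper`),
#'   overriding [default_bounds()].
#' @param start_factors multipliers of the reference means used as
#'   starting points (default: the means themselves plus 0.5x and 1.5x
#'   perturbations).
#' @param start_values optional explicit start(s): a named vector or a
#'   matrix with one start per row (overrides `start_factors`).
#' @param seed optional seed for the multiplicative jitter applied to
#'   the starts when `jitter_sd > 0`.
#' @param jitter_sd log-normal jitter of the starts (default 0: the
#'   start set is deterministic).
#' @param fixed named list of fixed parameters; defaults fix the Hill
#'   exponents `A_lipo = A_Cl = 2` and the FFA-Ra constants
#'   `m_F = 300`, `t_0F = 60`.  Set an entry to `NULL` to free it.
#' @param ftol,ptol,maxiter Levenberg-Marquardt termination controls
#'   (objective tolerance `1e-10`).
#' @param epsfcn forward-difference Jacobian step control; the default
#'   `1e-6` gives relative steps of about `1e-3`, safely above the ODE
#'   solver noise floor so numerical gradients stay informative.
#' @param engine,rtol,atol ODE solver options (see [simulate_model()]).
#' @param check_identifiability flag parameters whose +/-10 percent
#'   profile changes the objective by less than `1e-6`.
#' @return a list of class `ffamm_fit_config`.
#' @export
fit_config <- function(sigma2 = "subject", group = "AA",
                       bounds_multiplier = 5, bounds = NULL,
                       start_factors = c(1, 0.5, 1.5),
                       start_values = NULL, seed = NULL, jitter_sd = 0,
                       fixed = default_fixed(), ftol = 1e-10,
                       ptol = 1e-10, maxiter = 1000, epsfcn = 1e-6,
                       engine = "compiled", rtol = 1e-8, atol = 1e-8,
                       check_identifiability = TRUE) {
  structure(list(sigma2 = sigma2, group = group,
                 bounds_multiplier = bounds_multiplier, bounds = bounds,
                 start_factors = start_factors,
                 start_values = start_values, seed = seed,
                 jitter_sd = jitter_sd, fixed = fixed, ftol = ftol,
                 ptol = ptol, maxiter = maxiter, epsfcn = epsfcn,
                 engine = engine,
                 rtol = rtol, atol = atol,
                 check_identifiability = check_identifiability),
            class = "ffamm_fit_config")
}

#' Fit a model to one subject
#'
#' Estimates the free parameters of a model variant for one subject
#' under a simulation combination by bounded Levenberg-Marquardt
#' minimisation of the weighted objective (see [fit_objective()]),
#' from a configurable multi-start set.  Parameters are optimised on a
#' scale normalised by the reference means so that quantities spanning
#' six orders of magnitude are treated evenly.
#'
#' @param subject an `ffamm_subject` containing the protocols required
#'   by the combination.
#' @param model `"MOD1"`, `"MOD2"` or `"MOD3"`.
#' @param combo combination id or object; see [combination()].
#' @param config a [fit_config()].
#' @return an object of class `ffamm_fit`: estimated parameter objects
#'   (`params`, `ra_glucose`, `ra_ffa`), the named free-parameter vector
#'   `theta`, `objective`, the residual table, `n_data`, `k_free`,
#'   the `sigma2` weights used, convergence metadata (`converged`,
#'   `info`, `rsstrace`, `start_used`, `n_starts`) and the identifiability
#'   flags `flat_params`.
#' @export
fit_subject <- function(subject, model, combo, config = fit_config()) {
  stopifnot(inherits(subject, "ffamm_subject"))
  combo <- combination(combo)
  for (p in combo$protocols)
    if (is.null(subject[[p]]))
      stop("combination ", combo$id, " requires ", p,
           " data, which this subject lacks")
  free <- free_param_names(model, combo, config$fixed)
  bnds <- if (!is.null(config$bounds)) config$bounds
          else default_bounds(model, combo, config$group,
                              config$bounds_multiplier, config$fixed)
  lower <- bnds$lower[free]
  upper <- bnds$upper[free]
  ref <- if (!is.null(bnds$ref)) bnds$ref[free]
         else reference_means(model, combo$id, config$group)[free]
  s2 <- resolve_sigma2(subject, model, combo, config$sigma2)

  # start set
  if (!is.null(config$start_values)) {
    starts <- config$start_values
    if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1,
                                               dimnames = list(NULL, names(config$start_values)))
    if (!all(free %in% colnames(starts)))
      stop("start_values must provide all free parameters")
    starts <- starts[, free, drop = FALSE]
  } else {
    starts <- do.call(rbind, lapply(config$start_factors,
                                    function(f) f * ref))
    colnames(starts) <- free
  }
  if (config$jitter_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    starts <- starts * exp(matrix(rnorm(length(starts),
                                        sd = config$jitter_sd),
                                  nrow = nrow(starts)))
  }
  starts <- pmin(pmax(starts, rep(lower, each = nrow(starts))),
                 rep(upper, each = nrow(starts)))

  scale <- ref
  scale[!is.finite(scale) | scale <= 0] <- 1
  n_data <- nrow(residual_table(build_objects(model, setNames(starts[1, ], free),
                                              combo, config$fixed),
                                subject, combo, s2,
                                engine = config$engine,
                                rtol = config$rtol, atol = config$atol))
  resid_fn <- function(th_scaled) {
    theta <- setNames(th_scaled * scale, free)
    tab <- tryCatch({
      obj <- build_objects(model, theta, combo, config$fixed)
      residual_table(obj, subject, combo, s2, engine = config$engine,
                     rtol = config$rtol, atol = config$atol)
    }, error = function(e) NULL)
    if (is.null(tab)) return(rep(sqrt(1e12 / n_data), n_data))
    tab$resid / sqrt(tab$sigma2)
  }

  ctrl <- minpack.lm::nls.lm.control(ftol = config$ftol,
                                     ptol = config$ptol,
                                     maxiter = config$maxiter,
                                     epsfcn = config$epsfcn,
                                     maxfev = 100000L)
  best <- NULL
  best_start <- NA_integer_
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ] / scale,
                         lower = lower / scale, upper = upper / scale,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) {
      best <- res
      best_start <- i
    }
  }
  if (is.null(best))
    stop("all optimisation starts failed for model ", model,
         ", combination ", combo$id)

  theta <- setNames(unlist(best$par) * scale, free)
  objects <- build_objects(model, theta, combo, config$fixed)
  tab <- residual_table(objects, subject, combo, s2,
                        engine = config$engine, rtol = config$rtol,
                        atol = config$atol)
  objective <- sum(tab$resid^2 / tab$sigma2)

  flat <- character(0)
  if (isTRUE(config$check_identifiability)) {
    for (nm in free) {
      dd <- vapply(c(0.9, 1.1), function(f) {
        th <- theta; th[nm] <- th[nm] * f
        obj <- tryCatch(build_objects(model, th, combo, config$fixed),
                        error = function(e) NULL)
        if (is.null(obj)) return(NA_real_)
        o <- tryCatch(sum({
          t2 <- residual_table(obj, subject, combo, s2,
                               engine = config$engine,
                               rtol = config$rtol, atol = config$atol)
          t2$resid^2 / t2$sigma2
        }), error = function(e) NA_real_)
        abs(o - objective)
      }, numeric(1))
      if (all(is.finite(dd)) && max(dd) < 1e-6) flat <- c(flat, nm)
    }
  }

  structure(list(
    model = model, combination = combo$id, params = objects$params,
    ra_glucose = objects$ra_glucose, ra_ffa = objects$ra_ffa,
    theta = theta, objective = objective, residuals = tab,
    n_data = nrow(tab), k_free = length(free), sigma2 = s2,
    converged = best$info %in% 1:4, info = best$info,
    message = best$message, rsstrace = best$rsstrace,
    start_used = best_start, n_starts = nrow(starts),
    flat_params = flat, bounds = list(lower = lower, upper = upper)
  ), class = "ffamm_fit")
}

#' @export
print.ffamm_fit <- function(x, ...) {
  cat(sprintf("%s / %s fit: objective %.6g (n = %d, k = %d)%s\n",
              x$model, x$combination, x$objective, x$n_data, x$k_free,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(signif(x$theta, 4))
  if (length(x$flat_params))
    cat("flat (weakly identified) parameters:",
        paste(x$flat_params, collapse = ", "), "\n")
  invisible(x)
}
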