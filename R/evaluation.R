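## Model comparison and physiological indices.

#' Bayes information criterion of a fit
#'
#' Treats the weighted residual sum of squares (with known per-channel
#' variances) as a Gaussian deviance and penalises model complexity:
#' `BIC = objective + k_free * log(n_data)`.
#'
#' @param fit an `ffamm_fit` from [fit_subject()].
#' @return the BIC value.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "ffamm_fit"))
  if (fit$n_data == 0) stop("fit has no data points")
  fit$objective + fit$k_free * log(fit$n_data)
}

#' Normalised root mean square error of a fit
#'
#' RMSE per (protocol, channel), with residuals normalised by the
#' variance of the raw data used to weight the fit:
#' `sqrt(mean(resid^2 / sigma2))`.  Satisfies
#' `objective == sum over channels of n * rmse^2`.
#'
#' @param fit an `ffamm_fit`.
#' @param protocol `"FSIGT"` or `"MT"`.
#' @param channel `"glucose"` or `"ffa"`.
#' @return the normalised RMSE.
#' @export
rmse <- function(fit, protocol, channel) {
  stopifnot(inherits(fit, "ffamm_fit"))
  tab <- fit$residuals
  keep <- tab$protocol == protocol & tab$channel == channel
  if (!any(keep))
    stop("fit has no residuals for ", protocol, " ", channel)
  sqrt(mean(tab$resid[keep]^2 / tab$sigma2[keep]))
}

#' Acute insulin response to glucose (AIRg)
#'
#' Incremental area under the insulin curve between 0 and 10 min of the
#' IM-FSIGT, above the basal level, by the trapezoidal rule on the
#' sampled grid.  Basal insulin is the mean of the pre-zero samples
#' (the -10 and -1 min draws); if none are present it falls back to the
#' t = 0 value with a warning.  Excursions below basal contribute zero.
#'
#' @param insulin insulin series spanning \[0, 10\] min.
#' @return AIRg (uU/mL x min).
#' @export
airg <- function(insulin) {
  s <- as_series(insulin, "insulin")
  pre <- s$value[s$time < 0]
  basal <- if (length(pre)) mean(pre) else {
    i0 <- match(0, s$time)
    if (is.na(i0)) stop("insulin series has no samples at or before t = 0")
    warning("no pre-zero insulin samples; using I(0) as basal")
    s$value[i0]
  }
  keep <- s$time >= 0 & s$time <= 10
  if (sum(keep) < 2) stop("insulin series must span [0, 10] min")
  tt <- s$time[keep]
  inc <- pmax(s$value[keep] - basal, 0)
  sum(diff(tt) * (head_(inc) + tail_(inc)) / 2)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1L]

#' Disposition index
#'
#' The product of the acute insulin response to glucose and the insulin
#' sensitivity index, a measure of beta-cell compensation.
#'
#' @param airg_value AIRg (uU/mL x min), see [airg()].
#' @param S_I insulin sensitivity index (1/min per uU/mL).
#' @return `airg_value * S_I`.
#' @export
disposition_index <- function(airg_value, S_I) {
  stopifnot(is.finite(airg_value), is.finite(S_I),
            airg_value >= 0, S_I >= 0)
  airg_value * S_I
}

#' Model comparison table
#'
#' Summarises a set of fits into one row each: BIC and the per
#' (protocol, channel) normalised RMSEs (NA when a protocol/channel was
#' not fitted).
#'
#' @param fits a list of `ffamm_fit` objects.
#' @param subject_ids optional identifiers, recycled along `fits`.
#' @return a `data.frame` with columns `model`, `combination`,
#'   `subject`, `BIC`, `RMSE_FSIGT_G`, `RMSE_MT_G`, `RMSE_FSIGT_F`,
#'   `RMSE_MT_F`, `n_data`, `k_free`.
#' @export
compare_fits <- function(fits, subject_ids = seq_along(fits)) {
  if (inherits(fits, "ffamm_fit")) fits <- list(fits)
  subject_ids <- rep_len(subject_ids, length(fits))
  one <- function(fit, id) {
    cell <- function(p, ch) {
      tryCatch(rmse(fit, p, ch), error = function(e) NA_real_)
    }
    data.frame(model = fit$model, combination = fit$combination,
               subject = id, BIC = bic(fit),
               RMSE_FSIGT_G = cell("FSIGT", "glucose"),
               RMSE_MT_G = cell("MT", "glucose"),
               RMSE_FSIGT_F = cell("FSIGT", "ffa"),
               RMSE_MT_F = cell("MT", "ffa"),
               n_data = fit$n_data, k_free = fit$k_free)
  }
  do.call(rbind, Map(one, fits, subject_ids))
}

#' Write a comparison table to CSV
#'
#' @param comparison a table from [compare_fits()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  write.csv(comparison, path, row.names = FALSE)
  invisible(path)
}
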