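#' Construct a sampled time series
#'
#' A sampled series is the basic data container: paired (time, value)
#' measurements of one analyte for one subject and protocol.  Times are
#' minutes relative to the start of the test.
#'
#' @param time numeric vector of sampling times (min), strictly increasing.
#' @param value numeric vector of measurements, same length as `time`.
#' @return a `data.frame` with columns `time` and `value`.
#' @examples
#' sampled_series(c(0, 30, 60), c(92, 140, 120))
#' @export
sampled_series <- function(time, value) {
  if (length(time) != length(value))
    stop("'time' and 'value' must have the same length")
  if (length(time) == 0L)
    stop("empty series")
  if (!is.numeric(time) || !is.numeric(value))
    stop("'time' and 'value' must be numeric")
  if (anyNA(time) || any(!is.finite(time)))
    stop("non-finite sampling times")
  if (any(diff(time) <= 0))
    stop("sampling times must be strictly increasing")
  data.frame(time = as.numeric(time), value = as.numeric(value))
}

## coerce a two-column object to the (time, value) layout
as_series <- function(x, what = "series") {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x) && all(c("time", "value") %in% names(x)))
    return(sampled_series(x$time, x$value))
  if (is.data.frame(x) && ncol(x) == 2L)
    return(sampled_series(x[[1L]], x[[2L]]))
  stop("cannot interpret ", what, " as a sampled series")
}

#' Assemble per-subject tolerance-test data
#'
#' Bundles the insulin, glucose and FFA series of one subject for the
#' IM-FSIGT and/or meal-test protocol, together with the per-protocol,
#' per-channel residual variances used to weight the fitting objective.
#' Unmeasured channels may be omitted (`NULL`); insulin is required for
#' every protocol present because it is the model input.
#'
#' @param fsigt,mt named lists with elements `insulin`, `glucose`, `ffa`,
#'   each a series as returned by [sampled_series()] (or `NULL`).
#' @param sigma2 optional named list of variance vectors, e.g.
#'   `list(FSIGT = c(glucose = 25, ffa = 1e-3), MT = ...)`.  When absent,
#'   [fit_subject()] estimates variances with [estimate_variance()] or
#'   uses unit weights, depending on its configuration.
#' @return an object of class `ffamm_subject`.
#' @seealso [read_subject()], [synth_subject()]
#' @export
subject_data <- function(fsigt = NULL, mt = NULL, sigma2 = NULL) {
  if (is.null(fsigt) && is.null(mt))
    stop("at least one protocol (fsigt or mt) is required")
  check_block <- function(block, name) {
    if (is.null(block)) return(NULL)
    if (!is.list(block))
      stop("'", name, "' must be a list of series")
    out <- list(
      insulin = as_series(block$insulin, paste(name, "insulin")),
      glucose = as_series(block$glucose, paste(name, "glucose")),
      ffa     = as_series(block$ffa, paste(name, "ffa"))
    )
    if (is.null(out$insulin))
      stop("'", name, "' must contain an insulin series (model input)")
    out
  }
  structure(
    list(
      FSIGT  = check_block(fsigt, "fsigt"),
      MT     = check_block(mt, "mt"),
      sigma2 = sigma2
    ),
    class = "ffamm_subject"
  )
}

#' @export
print.ffamm_subject <- function(x, ...) {
  cat("ffamm subject data\n")
  for (p in c("FSIGT", "MT")) {
    if (is.null(x[[p]])) next
    ch <- names(Filter(Negate(is.null), x[[p]]))
    n <- vapply(Filter(Negate(is.null), x[[p]]), nrow, integer(1))
    cat(sprintf("  %-5s: %s\n", p,
                paste(sprintf("%s (n=%d)", ch, n), collapse = ", ")))
  }
  if (!is.null(x$sigma2)) cat("  sigma2: set\n")
  invisible(x)
}

## channels of a protocol block that carry data
present_channels <- function(subject, protocol) {
  block <- subject[[protocol]]
  if (is.null(block)) return(character())
  names(Filter(Negate(is.null), block[c("glucose", "ffa")]))
}
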