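#' Read subject data from CSV
#'
#' Reads one subject's tolerance-test data from a CSV file with columns
#' `protocol` (`FSIGT` or `MT`), `time_min`, `insulin`, `glucose`,
#' `ffa`.  Empty cells mark unmeasured channels; a channel that is empty
#' at every time point of a protocol is dropped for that protocol.
#' Units are assumed to be mg/dL (glucose), uU/mL (insulin) and mmol/L
#' (FFA); times are minutes.
#'
#' @param path path to the CSV file.
#' @return an `ffamm_subject` (see [subject_data()]).
#' @export
read_subject <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("protocol", "time_min", "insulin", "glucose", "ffa")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  for (col in c("time_min", "insulin", "glucose", "ffa")) {
    if (!is.numeric(raw[[col]]) && !all(is.na(raw[[col]]))) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at row ", bad[1L])
      raw[[col]] <- v
    }
  }
  blocks <- list()
  for (p in c("FSIGT", "MT")) {
    rows <- raw[raw$protocol == p, , drop = FALSE]
    if (!nrow(rows)) next
    if (any(duplicated(rows$time_min)))
      stop("duplicated time in protocol ", p, " at row ",
           which(raw$protocol == p)[which(duplicated(rows$time_min))[1L]])
    if (is.unsorted(rows$time_min, strictly = TRUE))
      stop("times must be strictly increasing within protocol ", p)
    one <- function(col) {
      keep <- !is.na(rows[[col]])
      if (!any(keep)) return(NULL)
      sampled_series(rows$time_min[keep], rows[[col]][keep])
    }
    blocks[[p]] <- list(insulin = one("insulin"), glucose = one("glucose"),
                        ffa = one("ffa"))
  }
  subject_data(fsigt = blocks$FSIGT, mt = blocks$MT)
}

#' Write subject data to CSV
#'
#' Inverse of [read_subject()]: serialises an `ffamm_subject` to the
#' `protocol,time_min,insulin,glucose,ffa` layout, one row per protocol
#' sample time, with empty cells for unmeasured channels.
#'
#' @param subject an `ffamm_subject`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subject <- function(subject, path) {
  stopifnot(inherits(subject, "ffamm_subject"))
  rows <- list()
  for (p in c("FSIGT", "MT")) {
    block <- subject[[p]]
    if (is.null(block)) next
    times <- sort(unique(unlist(lapply(Filter(Negate(is.null), block),
                                       `[[`, "time"))))
    grab <- function(s) {
      if (is.null(s)) return(rep(NA_real_, length(times)))
      s$value[match(times, s$time)]
    }
    rows[[p]] <- data.frame(protocol = p, time_min = times,
                            insulin = grab(block$insulin),
                            glucose = grab(block$glucose),
                            ffa = grab(block$ffa))
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory a trajectory from [simulate_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
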