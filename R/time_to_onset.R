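## Time from target-drug therapy initiation to adverse-event onset.

TTO_REASONS <- c("missing_start", "missing_event", "partial_date", "negative")

#' Compute per-case time to onset
#'
#' Onset time is the number of whole days from the earliest target-drug
#' therapy start date to the event date.  A case is excluded (with a reason
#' code) when either date is missing (`missing_start`, `missing_event`),
#' when either date has less than day precision (`partial_date`), or when
#' the difference is negative (`negative` -- an impossible "false positive"
#' onset).  Same-day onset (`tto = 0`) is retained.
#'
#' @param acases an `analysis_cases` object; only target cases are used.
#' @return data.frame with `primaryid`, `tto_days` (`NA` when excluded) and
#'   `excluded_reason` (`NA` when computable).
#' @export
compute_tto <- function(acases) {
  cases <- if (inherits(acases, "analysis_cases")) {
    acases$cases[acases$cases$is_target, , drop = FALSE]
  } else as.data.frame(acases)
  start <- as.character(cases$target_start_dt)
  event <- as.character(cases$event_dt)
  reason <- rep(NA_character_, nrow(cases))
  reason[is.na(event) | event == ""] <- "missing_event"
  reason[is.na(start) | start == ""] <- "missing_start"
  partial <- is.na(reason) & (nchar(start) < 8L | nchar(event) < 8L)
  reason[partial] <- "partial_date"
  tto <- rep(NA_real_, nrow(cases))
  ok <- is.na(reason)
  if (any(ok)) {
    d0 <- as.Date(start[ok], format = "%Y%m%d")
    d1 <- as.Date(event[ok], format = "%Y%m%d")
    bad <- is.na(d0) | is.na(d1)
    tto_ok <- as.numeric(d1 - d0)
    tto_ok[bad] <- NA
    reason[ok][bad] <- "partial_date"
    neg <- !bad & tto_ok < 0
    reason[ok][neg] <- "negative"
    tto_ok[neg] <- NA
    tto[ok] <- tto_ok
  }
  data.frame(primaryid = cases$primaryid, tto_days = tto,
             excluded_reason = reason, stringsAsFactors = FALSE)
}

#' Summarise the time-to-onset distribution
#'
#' @param tto numeric vector of onset days, or the data.frame returned by
#'   [compute_tto()] (excluded rows are dropped).
#' @param bin_edges upper edges (days) of the finite bins; the default
#'   `c(30, 60, 90, 180, 360)` yields bins 0-30, 31-60, 61-90, 91-180,
#'   181-360 and >360 days, each bin closed on the right.
#' @return list with `n`, `median` (mean of the two middle values for even
#'   `n`) and `bins`, a data.frame of `bin`, `count`, `percent` (2
#'   decimals).  Empty input gives `n = 0` and an empty bin table.
#' @export
summarize_tto <- function(tto, bin_edges = c(30, 60, 90, 180, 360)) {
  if (is.data.frame(tto)) tto <- tto$tto_days
  tto <- tto[!is.na(tto)]
  stopifnot(!is.unsorted(bin_edges), all(bin_edges > 0))
  labels <- c(sprintf("%d-%d", c(0, head(bin_edges, -1) + 1), bin_edges),
              sprintf(">%d", bin_edges[length(bin_edges)]))
  if (!length(tto)) {
    return(list(n = 0L, median = NA_real_,
                bins = data.frame(bin = labels, count = 0L, percent = NA_real_)))
  }
  idx <- findInterval(tto, c(bin_edges + 0.5))
  cnt <- tabulate(idx + 1L, nbins = length(labels))
  list(n = length(tto),
       median = median(tto),
       bins = data.frame(bin = labels, count = cnt,
                         percent = round(100 * cnt / length(tto), 2),
                         stringsAsFactors = FALSE))
}
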