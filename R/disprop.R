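## Disproportionality statistics on 2x2 contingency tables.
##
## For one drug-event pair the table is
##             event   other events
##   target      a          b
##   others      c          d
##
## Four classical screening algorithms are computed:
##   ROR  = ad/(bc),  95% CI = exp(ln ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d))
##   PRR  = a(c+d)/(c(a+b)),  with the Pearson chi-square
##   IC   = log2(aN/((a+b)(a+c)))  (BCPNN information component, simplified
##          observed/expected form), IC025 = IC - 2*sqrt(V) with V the
##          Bate et al. (1998) Beta/Dirichlet moment-approximation variance
##          with all prior hyperparameters equal to 1
##   EBGM = aN/((a+b)(a+c))  (simplified geometric-mean observed/expected),
##          EBGM05 = exp(ln EBGM - 1.96*sqrt(1/a+1/b+1/c+1/d))
## By construction IC == log2(EBGM).
##
## Signal criteria (all four must hold for a "significant" signal):
##   ROR:   lower 95% bound > 1 and a >= 3
##   PRR:   PRR >= 2 and chi-square >= 4 and a >= 3
##   BCPNN: IC025 > 0
##   MGPS:  EBGM05 > 2

#' Construct a 2x2 contingency table for one drug-event pair
#'
#' @param a,b,c,d non-negative counts: `a` target drug with the event, `b`
#'   target drug with other events, `c` other drugs with the event, `d` the
#'   remainder.
#' @param term event name.
#' @param level `"PT"` or `"SOC"`.
#' @param unit counting unit: `"report"` (each report counts once per term)
#'   or `"drug_event_pair"` (distinct report-term pairs; margins then count
#'   pairs).
#' @return object of class `contingency` with fields `a,b,c,d,N`.
#' @export
contingency_table <- function(a, b, c, d, term = "", level = "PT",
                              unit = "drug_event_pair") {
  level <- match.arg(level, c("PT", "SOC"))
  unit <- match.arg(unit, c("drug_event_pair", "report"))
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    data_error("contingency_table: cells must be non-negative counts")
  if (sum(cells) <= 0) data_error("contingency_table: N must be positive")
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d,
                 term = term, level = level, unit = unit),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency %s '%s' [%s]: a=%g b=%g c=%g d=%g N=%g>\n",
              x$level, x$term, x$unit, x$a, x$b, x$c, x$d, x$N))
  invisible(x)
}

# Zero-cell handling.  mode = "undefined": any of b, c, d equal to zero makes
# the ratio statistics non-computable (NA, criteria fail).  mode = "haldane":
# 0.5 is added to all four cells of affected tables.  a == 0 is never a
# signal under either mode.
apply_zero_policy <- function(a, b, c, d, mode = c("undefined", "haldane")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)   # doubles: cell products overflow
  c <- as.numeric(c); d <- as.numeric(d)   # 32-bit integers routinely
  zero <- b == 0 | c == 0 | d == 0
  computable <- a >= 1
  if (mode == "undefined") {
    computable <- computable & !zero
  } else {
    adj <- zero & a >= 1
    a <- a + 0.5 * adj; b <- b + 0.5 * adj
    c <- c + 0.5 * adj; d <- d + 0.5 * adj
  }
  list(a = a, b = b, c = c, d = d, computable = computable)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' Vectorised over cells.  `ror = a*d/(b*c)`; the CI is log-symmetric:
#' `exp(ln ror +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d numeric cell vectors (already zero-cell adjusted).
#' @param z normal quantile of the interval; the conventional printed value
#'   1.96 is used verbatim (not `qnorm(0.975)`) so results match published
#'   tables digit-for-digit.
#' @return data.frame with `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_stats <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.frame(ror = ror,
             ror_lo = exp(log(ror) - z * se),
             ror_hi = exp(log(ror) + z * se))
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `prr = a(c+d) / (c(a+b))`; the chi-square is the uncorrected Pearson
#' statistic `(ad-bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @inheritParams ror_stats
#' @return data.frame with `prr`, `chi2`.
#' @export
prr_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  prr <- a * (c + d) / (c * (a + b))
  chi2 <- (a * d - b * c)^2 * N / ((a + b) * (c + d) * (a + c) * (b + d))
  data.frame(prr = prr, chi2 = chi2)
}

#' BCPNN information component with moment-approximation credibility bound
#'
#' The point estimate is the simplified observed/expected ratio on the log2
#' scale, `ic = log2(a N / ((a+b)(a+c)))`, identical to `log2(ebgm)`.  The
#' lower bound is `ic025 = ic - 2 sqrt(V)` where `V` is the Bate et al.
#' (1998) moment approximation of the posterior variance of the information
#' component under independent Beta/Dirichlet priors with all hyperparameters
#' 1 (so alpha = beta = 2, alpha1 = beta1 = gamma11 = 1 and gamma chosen to
#' make the prior IC expectation zero).  The approximation is mildly
#' conservative relative to the exact posterior quantile for small `a`.
#'
#' @inheritParams ror_stats
#' @return data.frame with `ic`, `ic025`, `ic975`.
#' @export
bcpnn_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ic <- log2(a * N / ((a + b) * (a + c)))
  a1 <- 1; b1 <- 1; g11 <- 1; al <- 2; be <- 2
  g <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  V <- (1 / log(2))^2 * (
    (N - a + g - g11) / ((a + g11) * (1 + N + g)) +
    (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
    (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be)))
  s <- sqrt(V)
  data.frame(ic = ic, ic025 = ic - 2 * s, ic975 = ic + 2 * s)
}

#' Simplified empirical Bayes geometric mean with lower bound
#'
#' `ebgm = a N / ((a+b)(a+c))` (the observed/expected reporting ratio; no
#' gamma-Poisson mixture shrinkage) and
#' `ebgm05 = exp(ln ebgm - 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams ror_stats
#' @return data.frame with `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ebgm <- a * N / ((a + b) * (a + c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.frame(ebgm = ebgm, ebgm05 = exp(log(ebgm) - z * se))
}

# all four algorithms on vectors of raw cells, honouring the zero-cell policy
signal_stats_cells <- function(a, b, c, d,
                               zero_cell = c("undefined", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  p <- apply_zero_policy(a, b, c, d, zero_cell)
  out <- cbind(ror_stats(p$a, p$b, p$c, p$d),
               prr_stats(p$a, p$b, p$c, p$d),
               bcpnn_stats(p$a, p$b, p$c, p$d),
               ebgm_stats(p$a, p$b, p$c, p$d))
  out[!p$computable, ] <- NA_real_
  out
}

#' Compute the four disproportionality statistics for one table
#'
#' @param ct a [contingency_table()].
#' @param zero_cell zero-cell policy: `"undefined"` (default; a zero in
#'   `b`, `c` or `d` makes the row non-computable) or `"haldane"` (add 0.5
#'   to every cell of affected tables).  `a == 0` is never computable.
#' @return one-row data.frame with `ror, ror_lo, ror_hi, prr, chi2, ic,
#'   ic025, ic975, ebgm, ebgm05` (`NA` when non-computable).
#' @export
signal_stats <- function(ct, zero_cell = c("undefined", "haldane")) {
  stopifnot(inherits(ct, "contingency"))
  signal_stats_cells(ct$a, ct$b, ct$c, ct$d, match.arg(zero_cell))
}

#' Apply the four signal criteria
#'
#' `pass_ror`: ROR lower bound > 1 and a >= 3; `pass_prr`: PRR >= 2,
#' chi-square >= 4 and a >= 3; `pass_bcpnn`: IC025 > 0; `pass_mgps`:
#' EBGM05 > 2.  Non-computable statistics fail their criterion.
#' `significant` is the conjunction of all four.
#'
#' @param stats data.frame from [signal_stats()] (any number of rows).
#' @param a vector of `a` cell counts aligned with `stats`.
#' @return data.frame with the four logical flags and `significant`.
#' @export
evaluate_criteria <- function(stats, a) {
  isT <- function(x) !is.na(x) & x
  pass_ror <- isT(stats$ror_lo > 1) & a >= 3
  pass_prr <- isT(stats$prr >= 2) & isT(stats$chi2 >= 4) & a >= 3
  pass_bcpnn <- isT(stats$ic025 > 0)
  pass_mgps <- isT(stats$ebgm05 > 2)
  data.frame(pass_ror = pass_ror, pass_prr = pass_prr,
             pass_bcpnn = pass_bcpnn, pass_mgps = pass_mgps,
             significant = pass_ror & pass_prr & pass_bcpnn & pass_mgps)
}

# distinct (report, term) pairs at the requested level
event_pairs <- function(acases, level = c("PT", "SOC")) {
  level <- match.arg(level)
  ev <- acases$events
  if (level == "PT") {
    unique(data.frame(primaryid = ev$primaryid, term = ev$pt,
                      stringsAsFactors = FALSE))
  } else {
    ev <- ev[!is.na(ev$soc), , drop = FALSE]
    unique(data.frame(primaryid = ev$primaryid, term = ev$soc,
                      stringsAsFactors = FALSE))
  }
}

# contingency cells for every term at once; returns data.frame
# (term, a, b, c, d)
contingency_cells <- function(acases, level = c("PT", "SOC"),
                              unit = c("drug_event_pair", "report")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  pairs <- event_pairs(acases, level)
  tgt <- acases$cases$primaryid[acases$cases$is_target]
  pairs$is_target <- pairs$primaryid %in% tgt
  dt <- data.table::as.data.table(pairs)
  counts <- dt[, list(a = sum(is_target), c = sum(!is_target)), by = "term"]
  if (unit == "drug_event_pair") {
    n_t <- sum(dt$is_target)
    n_o <- nrow(dt) - n_t
  } else {
    n_t <- length(unique(dt$primaryid[dt$is_target]))
    n_o <- length(unique(dt$primaryid[!dt$is_target]))
  }
  counts$b <- n_t - counts$a
  counts$d <- n_o - counts$c
  as.data.frame(counts[, c("term", "a", "b", "c", "d")])
}

#' Build the 2x2 contingency table for one event term
#'
#' Under `unit = "report"`, `a` counts distinct target primary-suspect
#' reports containing the term (a report contributes at most once per term,
#' even when several of its PTs map to the same SOC) and the margins count
#' reports.  Under `unit = "drug_event_pair"` the counts are over distinct
#' (report, term) pairs and `N` is the total number of pairs at that level.
#'
#' @param acases an `analysis_cases` object.
#' @param term event term (PT or SOC name, matched after normalisation for
#'   PT level, verbatim for SOC).
#' @param level `"PT"` or `"SOC"`.
#' @param unit `"drug_event_pair"` (default) or `"report"`.
#' @return a [contingency_table()]; a term observed nowhere gives `a = 0`.
#' @export
build_contingency <- function(acases, term,
                              level = c("PT", "SOC"),
                              unit = c("drug_event_pair", "report")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  if (!nzchar(trimws(term))) config_error("build_contingency: empty term")
  cells <- contingency_cells(acases, level, unit)
  key <- if (level == "PT") norm_key(term) else trimws(term)
  row <- cells[cells$term == key, , drop = FALSE]
  if (!nrow(row)) {
    # term absent everywhere: a = 0 with the full margins
    n_t <- if (unit == "report") {
      length(unique(acases$cases$primaryid[acases$cases$is_target]))
    } else sum(event_pairs(acases, level)$primaryid %in%
                 acases$cases$primaryid[acases$cases$is_target])
    pairs <- event_pairs(acases, level)
    tot <- if (unit == "report") nrow(acases$cases) else nrow(pairs)
    row <- data.frame(term = key, a = 0L, b = n_t, c = 0L,
                      d = tot - n_t)
    row$c <- 0L
    row$d <- tot - n_t
  }
  contingency_table(row$a, row$b, row$c, row$d, term = key,
                    level = level, unit = unit)
}

#' Screen every event term for disproportionality signals
#'
#' Builds all contingency tables at the requested level, computes the four
#' algorithms (vectorised), applies the criteria, drops terms matching the
#' exclusion list (terms considered unrelated to drug treatment, matched
#' against both the term itself and its SOC), and ranks the result.
#'
#' @param acases an `analysis_cases` object.
#' @param level `"PT"` or `"SOC"`.
#' @param unit counting unit, see [build_contingency()].
#' @param zero_cell zero-cell policy, see [signal_stats()].
#' @param exclusions character vector of SOC and/or PT names to drop before
#'   counting significant signals (default none; see
#'   [default_exclusions()]).
#' @param rank_by `"count"` (descending `a`, the report-frequency ordering)
#'   or `"ebgm"` (descending signal strength).
#' @param min_a drop rows with `a` below this (default 0: every term
#'   observed anywhere gets a row, with `a = 0` rows non-computable).
#' @return data.frame of class `signal_table`: one row per term with columns
#'   `level, term, soc, a, b, c, d`, the ten statistics, the four criterion
#'   flags, `significant` and `unexpected` (`NA` until
#'   [flag_unexpected()] is applied).
#' @export
screen_signals <- function(acases,
                           level = c("PT", "SOC"),
                           unit = c("drug_event_pair", "report"),
                           zero_cell = c("undefined", "haldane"),
                           exclusions = NULL,
                           rank_by = c("count", "ebgm"),
                           min_a = 0) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  zero_cell <- match.arg(zero_cell)
  rank_by <- match.arg(rank_by)
  cells <- contingency_cells(acases, level, unit)
  if (level == "PT") {
    soc <- acases$events$soc[match(cells$term, acases$events$pt)]
  } else soc <- cells$term
  keep <- cells$a >= min_a
  cells <- cells[keep, , drop = FALSE]
  soc <- soc[keep]
  if (!is.null(exclusions) && length(exclusions)) {
    ex <- norm_key(exclusions)
    drop <- norm_key(cells$term) %in% ex | norm_key(soc) %in% ex
    cells <- cells[!drop, , drop = FALSE]
    soc <- soc[!drop]
  }
  stats <- signal_stats_cells(cells$a, cells$b, cells$c, cells$d, zero_cell)
  crit <- evaluate_criteria(stats, cells$a)
  out <- cbind(data.frame(level = rep(level, nrow(cells)), term = cells$term,
                          soc = soc, stringsAsFactors = FALSE),
               cells[, c("a", "b", "c", "d")],
               stats[, c("ror", "ror_lo", "ror_hi", "prr", "chi2",
                         "ic", "ic025", "ebgm", "ebgm05")],
               crit)
  out$unexpected <- NA
  ord <- if (rank_by == "count") order(-out$a, out$term)
         else order(-ifelse(is.na(out$ebgm), -Inf, out$ebgm), out$term)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unit") <- unit
  attr(out, "zero_cell") <- zero_cell
  class(out) <- c("signal_table", "data.frame")
  out
}

#' Default exclusion terms for treatment-unrelated signals
#'
#' SOC groups conventionally screened out before counting significant
#' signals: product issues, injuries/poisonings/procedural complications,
#' and surgical or medical procedures.
#'
#' @return character vector of SOC names.
#' @export
default_exclusions <- function() {
  c("Product issues",
    "Injury, poisoning and procedural complications",
    "Surgical and medical procedures")
}

#' Flag unexpected (label-undocumented) signals
#'
#' A signal is unexpected when it is significant and its term is absent from
#' the supplied list of label-documented PTs.  With `label_pts = NULL` the
#' flag is left undetermined (`NA`).
#'
#' @param signals a `signal_table` from [screen_signals()].
#' @param label_pts character vector of label-documented PT names, or `NULL`.
#' @return the signal table with `unexpected` filled in.
#' @export
flag_unexpected <- function(signals, label_pts = NULL) {
  if (is.null(label_pts)) {
    signals$unexpected <- NA
    return(signals)
  }
  lab <- norm_key(label_pts)
  signals$unexpected <- signals$significant &
    !norm_key(signals$term) %in% lab
  signals
}
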