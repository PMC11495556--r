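## Synthetic FAERS-like report generator with known ground truth.
##
## The generator emulates the report-level structure of a quarterly FAERS
## slice: demographics, multi-drug records with role codes, multi-PT
## reaction records, therapy and event dates, outcomes, duplicate case
## versions -- and plants configurable drug-event reporting-rate ratios so
## that signal recovery can be checked against a known truth.

#' Configuration of the synthetic report generator
#'
#' Defaults describe a deliberately FAERS-like world: a rare target drug
#' (2\% of reports; large enough that planted rare-event signals reach
#' detectable case counts at desk scale), a Zipf-distributed PT vocabulary,
#' about three PTs per report (zero-truncated Poisson), mostly male elderly
#' patients, consumer reporters, US-dominated countries, a log-normal
#' onset-time distribution with 60-day median, 5\% duplicate case versions
#' and FAERS-typical missingness (ages missing for ~60\% of reports, most
#' reports carrying no outcome code).
#'
#' @param n_reports number of distinct cases to simulate.
#' @param p_target probability that a report's primary-suspect drug is the
#'   target drug.
#' @param n_pts size of the PT vocabulary (terms `PT_001` ...).
#' @param baseline_probs event probability vector of length `n_pts`
#'   (normalised); default Zipf (`1/j`).
#' @param planted named numeric vector of reporting-rate ratios `lambda`
#'   (names are PT terms); unnamed PTs have `lambda = 1`.  For a
#'   target-exposed report the event weights are
#'   `baseline_probs * lambda`, renormalised.
#' @param events_mean rate of the zero-truncated Poisson number of distinct
#'   PTs per report.
#' @param dup_fraction fraction of cases re-emitted as a follow-up version
#'   (new `primaryid`, `caseversion + 1`, `fda_dt + 30` days).
#' @param missing_rates list of per-field missingness probabilities:
#'   `event_dt`, `start_dt`, `partial_date` (present dates degraded to
#'   month precision), `age`, `sex`, `country`, `occp`.
#' @param tto_median,tto_sigma log-normal onset-time parameters: median in
#'   days and log-scale standard deviation.
#' @param demo_probs categorical distributions for sex, age (normal mean/sd
#'   in years), country, reporter occupation and outcome (`none` = report
#'   carries no outcome code).
#' @param n_decoys size of the decoy primary-suspect drug vocabulary for
#'   non-target reports.
#' @param target_names drug name strings emitted for target reports (the
#'   first is also the `prod_ai`).
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 300000,
                             p_target = 0.02,
                             n_pts = 200,
                             baseline_probs = NULL,
                             planted = numeric(0),
                             events_mean = 3,
                             dup_fraction = 0.05,
                             missing_rates = list(),
                             tto_median = 60,
                             tto_sigma = 1,
                             demo_probs = list(),
                             n_decoys = 50,
                             target_names = c("RELUGOLIX", "ORGOVYX"),
                             seed = 20201001) {
  if (is.null(baseline_probs)) baseline_probs <- 1 / seq_len(n_pts)
  if (length(baseline_probs) != n_pts)
    config_error("baseline_probs must have length n_pts")
  if (any(baseline_probs < 0)) config_error("baseline_probs must be >= 0")
  baseline_probs <- baseline_probs / sum(baseline_probs)
  if (length(planted)) {
    if (is.null(names(planted)) || any(!nzchar(names(planted))))
      config_error("planted must be a named vector (PT term -> lambda)")
    if (any(planted < 0)) config_error("planted lambdas must be >= 0")
    if (length(planted) > n_pts)
      config_error("more planted PTs than the vocabulary holds")
  }
  mr <- modifyList(list(event_dt = 0.5, start_dt = 0.35, partial_date = 0.1,
                        age = 0.6, sex = 0.02, country = 0.03, occp = 0.05),
                   missing_rates)
  dp <- modifyList(list(
    sex = c(M = 0.95, F = 0.03, UNK = 0.02),
    age_mean = 72, age_sd = 12,
    country = c(US = 0.9682, JP = 0.0202, DE = 0.0039, PT = 0.0016,
                SE = 0.0014, FR = 0.002, GB = 0.002, CA = 0.0007),
    occp = c(CN = 0.84, HP = 0.10, MD = 0.05, PH = 0.01),
    outcome = c(none = 0.824, OT = 0.072, HO = 0.054, DE = 0.048,
                DS = 0.001, LT = 0.001)
  ), demo_probs)
  rates <- unlist(mr)
  if (any(rates < 0 | rates > 1))
    config_error("missing_rates must be probabilities")
  if (p_target < 0 || p_target > 1 || dup_fraction < 0 || dup_fraction > 1)
    config_error("p_target and dup_fraction must be probabilities")
  # infeasible when the events-per-report distribution effectively exceeds
  # the vocabulary
  if (stats::qpois(1 - 1e-9, events_mean) > n_pts)
    config_error("events_mean too large for the PT vocabulary (n_pts)")
  structure(list(
    n_reports = as.integer(n_reports), p_target = p_target,
    n_pts = as.integer(n_pts), baseline_probs = baseline_probs,
    planted = planted, events_mean = events_mean,
    dup_fraction = dup_fraction, missing_rates = mr,
    tto_median = tto_median, tto_sigma = tto_sigma, demo_probs = dp,
    n_decoys = as.integer(n_decoys), target_names = target_names,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# zero-truncated Poisson (rejection-free via inverse CDF on the truncated
# distribution)
rztpois <- function(n, lambda) {
  u <- runif(n, min = stats::dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

# Draw k[i] distinct items for each of length(k) rows, with probability
# proportional to w, via exponential ranking keys (weighted sampling without
# replacement), chunked to bound memory.  Returns an integer vector of the
# selected item indices, grouped row-by-row (use rep(row_id, k) to align).
sample_events_weighted <- function(k, w) {
  m_all <- length(k)
  p <- length(w)
  if (!m_all) return(integer(0))
  kmax_all <- max(k)
  stopifnot(kmax_all <= p)
  chunk <- max(1L, floor(4e6 / p))
  out <- vector("list", ceiling(m_all / chunk))
  for (ci in seq_along(out)) {
    lo <- (ci - 1L) * chunk + 1L
    hi <- min(ci * chunk, m_all)
    kk <- k[lo:hi]
    m <- length(kk)
    kmax <- max(kk)
    E <- matrix(rexp(m * p), m, p) / rep(w, each = m)
    sel <- matrix(0L, m, kmax)
    for (r in seq_len(kmax)) {
      j <- max.col(-E, ties.method = "first")
      sel[, r] <- j
      E[cbind(seq_len(m), j)] <- Inf
    }
    mask <- matrix(seq_len(kmax), m, kmax, byrow = TRUE) <= kk
    out[[ci]] <- t(sel)[t(mask)]   # row-major: events grouped per report
  }
  unlist(out)
}

#' Generate a synthetic FAERS-like dataset with known ground truth
#'
#' Reports are sampled independently.  For a target-exposed report the event
#' weights are `baseline_probs * lambda`, renormalised; events are drawn
#' without replacement up to the report's event count.  Therapy start and
#' event dates are placed so that `event - start` follows the configured
#' log-normal onset model; missingness then degrades fields.  Duplicates are
#' re-emissions of a case with incremented `caseversion`, a new `primaryid`
#' and `fda_dt + 30` days.  Everything is reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; when given, the five quarterly
#'   tables, the PT-to-SOC map (`syn_MEDDRA.txt`) and a ground-truth sidecar
#'   (`syn_TRUTH.json`) are written there.
#' @return list with `bundle` (a [faers_bundle()]), `truth` (planted
#'   lambdas, renormalisation constant, duplicate linkage, true onset
#'   times), `map` (the [meddra_map()]), `config`, and `paths` (when `dir`
#'   was given).
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  p <- config$n_pts
  pt_names <- sprintf("PT_%03d", seq_len(p))
  soc_names <- sprintf("SOC_%02d", ((seq_len(p) - 1L) %% 20L) + 1L)
  map <- meddra_map(pt_names, soc_names)

  lambda <- setNames(rep(1, p), pt_names)
  if (length(config$planted)) {
    unknown <- setdiff(names(config$planted), pt_names)
    if (length(unknown))
      config_error(sprintf("planted PT(s) not in vocabulary: %s",
                           paste(unknown, collapse = ", ")))
    lambda[names(config$planted)] <- config$planted
  }
  w0 <- config$baseline_probs
  wt <- w0 * lambda
  renorm <- sum(wt)
  wt <- wt / renorm

  caseid <- as.character(20000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")
  is_target <- runif(n) < config$p_target

  ## events
  k <- pmin(rztpois(n, config$events_mean), p)
  idx_t <- which(is_target)
  idx_o <- which(!is_target)
  ev_t <- sample_events_weighted(k[idx_t], wt)
  ev_o <- sample_events_weighted(k[idx_o], w0)
  reac <- data.frame(
    primaryid = c(rep(primaryid[idx_t], k[idx_t]),
                  rep(primaryid[idx_o], k[idx_o])),
    pt = pt_names[c(ev_t, ev_o)],
    stringsAsFactors = FALSE)

  ## dates: therapy start, event (= start + onset), fda receipt
  mr <- config$missing_rates
  start_date <- as.Date("2020-10-01") +
    floor(runif(n, 0, as.numeric(as.Date("2023-06-30") - as.Date("2020-10-01")) + 1))
  tto_true <- round(rlnorm(n, meanlog = log(config$tto_median),
                           sdlog = config$tto_sigma))
  event_date <- start_date + tto_true
  fda_date <- event_date + floor(runif(n, 0, 61))

  fmt <- function(d) format(d, "%Y%m%d")
  start_str <- fmt(start_date)
  event_str <- fmt(event_date)
  # degrade some present dates to month precision, then knock out others
  deg <- runif(n) < mr$partial_date
  start_str[deg] <- substr(start_str[deg], 1, 6)
  deg2 <- runif(n) < mr$partial_date
  event_str[deg2] <- substr(event_str[deg2], 1, 6)
  start_str[runif(n) < mr$start_dt] <- NA_character_
  event_str[runif(n) < mr$event_dt] <- NA_character_

  ## demographics
  dp <- config$demo_probs
  sex <- sample(names(dp$sex), n, replace = TRUE, prob = dp$sex)
  sex[runif(n) < mr$sex] <- NA_character_
  age_years <- pmin(pmax(rnorm(n, dp$age_mean, dp$age_sd), 0.5), 105)
  age_cod <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                    prob = c(0.97, 0.02, 0.01))
  age_val <- round(ifelse(age_cod == "YR", age_years,
                          ifelse(age_cod == "DEC", age_years / 10,
                                 age_years * 12)), 1)
  miss_age <- runif(n) < mr$age
  age_val[miss_age] <- NA_real_
  age_cod[miss_age] <- NA_character_
  country <- sample(names(dp$country), n, replace = TRUE, prob = dp$country)
  country[runif(n) < mr$country] <- NA_character_
  occp <- sample(names(dp$occp), n, replace = TRUE, prob = dp$occp)
  occp[runif(n) < mr$occp] <- NA_character_

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = 1L,
    fda_dt = fmt(fda_date), event_dt = event_str, rept_dt = fmt(fda_date),
    age = age_val, age_cod = age_cod, sex = sex,
    reporter_country = country, occp_cod = occp, stringsAsFactors = FALSE)

  ## drugs: one PS row per report; ~30% get a concomitant decoy
  decoys <- sprintf("DRUG_%03d", seq_len(config$n_decoys))
  # mixed case exercises name normalisation; fields stay trimmed so that
  # written files read back identical
  tgt_styles <- c(config$target_names, tolower(config$target_names[[1]]))
  ps_name <- character(n)
  ps_name[idx_t] <- sample(tgt_styles, length(idx_t), replace = TRUE)
  ps_name[idx_o] <- sample(decoys, length(idx_o), replace = TRUE)
  ps_ai <- ifelse(is_target, config$target_names[[1]], ps_name)
  drug <- data.frame(primaryid = primaryid, drug_seq = 1L, role_cod = "PS",
                     drugname = ps_name, prod_ai = ps_ai,
                     stringsAsFactors = FALSE)
  con <- which(runif(n) < 0.3)
  if (length(con)) {
    drug <- rbind(drug, data.frame(
      primaryid = primaryid[con], drug_seq = 2L, role_cod = "C",
      drugname = sample(decoys, length(con), replace = TRUE),
      prod_ai = NA_character_, stringsAsFactors = FALSE))
  }

  ## therapy rows for the PS drug (only when a start date survived)
  has_start <- !is.na(start_str)
  ther <- data.frame(primaryid = primaryid[has_start], dsg_drug_seq = 1L,
                     start_dt = start_str[has_start],
                     end_dt = NA_character_, stringsAsFactors = FALSE)

  ## outcomes
  oc <- sample(names(dp$outcome), n, replace = TRUE, prob = dp$outcome)
  keep_oc <- oc != "none"
  outc <- data.frame(primaryid = primaryid[keep_oc], outc_cod = oc[keep_oc],
                     stringsAsFactors = FALSE)
  # a few cases carry a second outcome code (exercises precedence collapse)
  extra <- which(keep_oc & runif(n) < 0.05)
  if (length(extra)) {
    codes <- setdiff(names(dp$outcome), "none")
    outc <- rbind(outc, data.frame(
      primaryid = primaryid[extra],
      outc_cod = sample(codes, length(extra), replace = TRUE,
                        prob = dp$outcome[codes]),
      stringsAsFactors = FALSE))
  }

  ## duplicate case versions: later fda_dt, caseversion 2, new primaryid
  n_dup <- round(config$dup_fraction * n)
  dup_idx <- if (n_dup) sort(sample.int(n, n_dup)) else integer(0)
  if (n_dup) {
    dup_pid <- paste0(caseid[dup_idx], "2")
    d2 <- demo[dup_idx, , drop = FALSE]
    d2$primaryid <- dup_pid
    d2$caseversion <- 2L
    d2$fda_dt <- fmt(fda_date[dup_idx] + 30)
    d2$rept_dt <- d2$fda_dt
    demo <- rbind(demo, d2)
    clone <- function(df) {
      sel <- df[df$primaryid %in% primaryid[dup_idx], , drop = FALSE]
      sel$primaryid <- paste0(substr(sel$primaryid, 1,
                                     nchar(sel$primaryid) - 1L), "2")
      sel
    }
    drug <- rbind(drug, clone(drug))
    reac <- rbind(reac, clone(reac))
    ther <- rbind(ther, clone(ther))
    outc <- rbind(outc, clone(outc))
  }

  bundle <- faers_bundle(demo, drug, reac, ther, outc,
                         quarter_label = "SYN")
  truth <- list(
    lambda = lambda,
    baseline_probs = setNames(w0, pt_names),
    renorm = renorm,
    p_target = config$p_target,
    duplicates = data.frame(caseid = caseid[dup_idx],
                            primaryid_orig = primaryid[dup_idx],
                            primaryid_dup = if (n_dup)
                              paste0(caseid[dup_idx], "2") else character(0),
                            stringsAsFactors = FALSE),
    tto_true = data.frame(primaryid = primaryid, tto_days = tto_true,
                          stringsAsFactors = FALSE),
    is_target = setNames(is_target, primaryid)
  )
  out <- list(bundle = bundle, truth = truth, map = map, config = config)
  if (!is.null(dir)) {
    paths <- write_quarter_tables(bundle, dir, prefix = "syn")
    map_path <- file.path(dir, "syn_MEDDRA.txt")
    utils::write.table(as.data.frame(map), map_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth_path <- file.path(dir, "syn_TRUTH.json")
    jsonlite::write_json(
      list(lambda = as.list(lambda), renorm = renorm,
           p_target = config$p_target, seed = config$seed,
           n_duplicates = n_dup),
      truth_path, auto_unbox = TRUE, digits = NA)
    out$paths <- c(paths, meddra = map_path, truth = truth_path)
  }
  out
}

#' Check recovery of planted signals against the ground truth
#'
#' For each planted PT with `lambda >= 5` and expected case count `a` of at
#' least `min_expected_a`, the screened EBGM must lie within `tolerance`
#' (relative) of the planted ratio adjusted for the generator's weight
#' renormalisation: the effective per-pair rate ratio of a planted PT is
#' `r = lambda / renorm`, and the observed/expected ratio against the pooled
#' margins is `r / (p_target * r + 1 - p_target)`.  PTs with `lambda = 1`
#' form the null set; their significant-flag rate must stay below
#' `fp_budget`.
#'
#' @param signals a `signal_table` from [screen_signals()] at PT level.
#' @param truth the `truth` component of [generate_dataset()].
#' @param config the [synthetic_config()] used.
#' @param tolerance relative EBGM tolerance for planted PTs (default 0.3).
#' @param fp_budget maximum fraction of null PTs flagged significant.
#' @param min_expected_a planted PTs below this expected count are reported
#'   but not gated.
#' @return list with `planted` (per-PT recovery table), `fp_rate`, `n_null`
#'   and `pass`.
#' @export
planted_truth_check <- function(signals, truth, config, tolerance = 0.3,
                                fp_budget = 0.02, min_expected_a = 50) {
  lam <- truth$lambda
  planted_pts <- names(lam)[lam != 1]
  kbar <- config$events_mean / (1 - exp(-config$events_mean))
  wt <- truth$baseline_probs * lam / truth$renorm
  n_t <- config$n_reports * config$p_target
  res <- lapply(planted_pts, function(pt) {
    r <- lam[[pt]] / truth$renorm
    target_val <- r / (config$p_target * r + 1 - config$p_target)
    expected_a <- n_t * (1 - (1 - wt[[pt]])^kbar)
    row <- signals[norm_key(signals$term) == norm_key(pt), , drop = FALSE]
    ebgm <- if (nrow(row)) row$ebgm[[1]] else NA_real_
    sig <- if (nrow(row)) row$significant[[1]] else FALSE
    eligible <- lam[[pt]] >= 5 && expected_a >= min_expected_a
    ok <- !eligible ||
      (!is.na(ebgm) && abs(ebgm - target_val) <= tolerance * target_val)
    data.frame(pt = pt, lambda = lam[[pt]], target = target_val,
               expected_a = expected_a, ebgm = ebgm, significant = sig,
               eligible = eligible, ok = ok, stringsAsFactors = FALSE)
  })
  planted_df <- if (length(res)) do.call(rbind, res) else
    data.frame(pt = character(0))
  null_pts <- norm_key(names(lam)[lam == 1])
  null_rows <- signals[norm_key(signals$term) %in% null_pts, , drop = FALSE]
  fp_rate <- if (nrow(null_rows)) mean(null_rows$significant) else 0
  list(planted = planted_df, fp_rate = fp_rate, n_null = nrow(null_rows),
       pass = all(planted_df$ok %||% TRUE) && fp_rate <= fp_budget)
}
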