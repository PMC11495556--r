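## Case deduplication, primary-suspect filtering and MedDRA standardisation.

#' Deduplicate FAERS cases
#'
#' FAERS carries multiple versions of the same case (follow-up reports share
#' a `caseid` but get a new `primaryid`).  The FDA-recommended rule is
#' applied: per `caseid`, keep the report with the latest `fda_dt`; ties are
#' broken by the numerically largest `primaryid`.  Missing `fda_dt` sorts as
#' the earliest possible date, so a dated version always wins.
#'
#' @param demo DEMO data.frame (columns `primaryid`, `caseid`, `fda_dt`).
#' @return character vector of retained `primaryid`s, with attribute
#'   `removed` giving the number of dropped duplicate reports.
#' @export
deduplicate_cases <- function(demo) {
  if (!NROW(demo)) data_error("deduplicate_cases: empty DEMO table")
  dt <- data.table::data.table(
    primaryid = as.character(demo$primaryid),
    caseid = norm_key(demo$caseid),
    fda_key = pad_dt(demo$fda_dt),
    pid_num = suppressWarnings(as.numeric(demo$primaryid))
  )
  # deterministic order: latest fda_dt first, then largest numeric primaryid,
  # then lexicographic primaryid as a last resort
  data.table::setorder(dt, caseid, -fda_key, -pid_num, -primaryid,
                       na.last = TRUE)
  keep <- dt[, .SD[1L], by = "caseid"]$primaryid
  structure(sort(keep), removed = nrow(dt) - length(keep))
}

#' Find reports naming a target drug
#'
#' A report matches when any of its drug rows with the requested role code
#' has `drugname` or `prod_ai` equal (after trim/upper-case normalisation)
#' to any of the supplied names.  With `substring = TRUE` a normalised
#' substring match is used instead, which tolerates verbatim-name noise at
#' the cost of catching combination products.
#'
#' @param drug DRUG data.frame.
#' @param names character vector of target drug names (generic and/or trade).
#' @param role role code filter, default `"PS"` (primary suspect).
#' @param substring use substring matching instead of exact equality.
#' @return character vector of matching `primaryid`s (unique, sorted).
#' @export
match_target_drug <- function(drug, names, role = "PS", substring = FALSE) {
  names <- norm_key(names)
  names <- names[!is.na(names)]
  if (!length(names)) config_error("target drug name list is empty")
  role <- match.arg(norm_key(role), ROLE_CODES)
  d <- drug[norm_key(drug$role_cod) == role, , drop = FALSE]
  if (!nrow(d)) return(character(0))
  dn <- norm_key(d$drugname)
  ai <- norm_key(d$prod_ai)
  if (substring) {
    hit <- rep(FALSE, nrow(d))
    for (nm in names)
      hit <- hit | grepl(nm, dn, fixed = TRUE) | grepl(nm, ai, fixed = TRUE)
    hit[is.na(hit)] <- FALSE
  } else {
    hit <- (dn %in% names) | (ai %in% names)
  }
  sort(unique(as.character(d$primaryid[hit])))
}

#' Construct a PT to SOC map
#'
#' Stand-in for a licensed MedDRA distribution: each preferred term maps to
#' exactly one (primary) System Organ Class.  Conflicting duplicate entries
#' are a fatal error; exact duplicates are collapsed.
#'
#' @param pt,soc character vectors of equal length.
#' @return an object of class `meddra_map` (a keyed data.frame).
#' @export
meddra_map <- function(pt, soc) {
  key <- norm_key(pt)
  ok <- !is.na(key) & !is.na(soc)
  df <- unique(data.frame(pt = key[ok], soc = trimws(as.character(soc[ok])),
                          stringsAsFactors = FALSE))
  if (anyDuplicated(df$pt))
    data_error("meddra_map: some PTs map to more than one SOC")
  class(df) <- c("meddra_map", "data.frame")
  df
}

#' Read a PT to SOC map from a delimited file
#'
#' Expects a header row naming columns `pt` and `soc`; the delimiter is
#' sniffed from the header (tab, comma or dollar).
#'
#' @param path file path.
#' @return a [meddra_map()].
#' @export
read_meddra_map <- function(path) {
  if (!file.exists(path)) data_error(sprintf("MedDRA map not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) ","
         else if (grepl("\\$", first)) "$" else "\t"
  df <- utils::read.delim(path, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("pt", "soc") %in% names(df)))
    data_error(sprintf("MedDRA map '%s' must have columns 'pt' and 'soc'",
                       path))
  meddra_map(df$pt, df$soc)
}

#' Standardise event terms against a PT to SOC map
#'
#' PTs are case/whitespace-normalised and looked up.  Unmapped PTs are kept
#' (the PT-level statistics need no SOC) but excluded from SOC-level sets.
#'
#' @param pts character vector of preferred-term strings.
#' @param map a [meddra_map()].
#' @return list with `pts` (normalised unique PTs), `socs` (unique SOCs of
#'   the mapped PTs) and `unmapped` (PTs absent from the map).
#' @export
standardize_terms <- function(pts, map) {
  stopifnot(inherits(map, "meddra_map"))
  if (!nrow(map)) config_error("standardize_terms: empty MedDRA map")
  pts <- unique(norm_key(pts))
  pts <- pts[!is.na(pts)]
  idx <- match(pts, map$pt)
  list(pts = pts,
       socs = unique(map$soc[idx[!is.na(idx)]]),
       unmapped = pts[is.na(idx)])
}

#' Assemble the per-case analysis table
#'
#' Runs the preprocessing chain on a bundle: deduplicate cases, flag reports
#' where the target drug is primary suspect, normalise PTs and attach SOCs,
#' pull per-case demographics, outcomes and therapy start dates.  The flow
#' manifest mirrors the study-flow accounting: total reports, reports after
#' deduplication, and target primary-suspect reports.
#'
#' Cases whose reaction set is empty after normalisation are dropped with a
#' warning (a report with no event cannot enter any analysis).
#'
#' @param bundle a [faers_bundle()].
#' @param target_names character vector of target drug names.
#' @param map a [meddra_map()].
#' @param role drug role defining "target exposed", default `"PS"`.
#' @param substring passed to [match_target_drug()].
#' @param year_field DEMO date field whose year is the "reporting year"
#'   (`"fda_dt"`, always populated, or `"rept_dt"`).
#' @return an object of class `analysis_cases`: list with `cases` (one row
#'   per retained report), `events` (long `primaryid`/`pt`/`soc` table,
#'   `soc` is `NA` for unmapped PTs), `outcomes` (long), `manifest` (stage
#'   counts) and `unmapped` (distinct unmapped PTs).
#' @export
assemble_case_table <- function(bundle, target_names, map, role = "PS",
                                substring = FALSE, year_field = "fda_dt") {
  stopifnot(inherits(bundle, "faers_bundle"), inherits(map, "meddra_map"))
  year_field <- match.arg(year_field, c("fda_dt", "rept_dt"))
  n_total <- nrow(bundle$demo)
  keep <- deduplicate_cases(bundle$demo)
  demo <- bundle$demo[as.character(bundle$demo$primaryid) %in% keep, ,
                      drop = FALSE]
  n_dedup <- nrow(demo)
  ids <- as.character(demo$primaryid)

  drug <- bundle$drug[as.character(bundle$drug$primaryid) %in% ids, ,
                      drop = FALSE]
  reac <- bundle$reac[as.character(bundle$reac$primaryid) %in% ids, ,
                      drop = FALSE]
  ther <- bundle$ther[as.character(bundle$ther$primaryid) %in% ids, ,
                      drop = FALSE]
  outc <- bundle$outc[as.character(bundle$outc$primaryid) %in% ids, ,
                      drop = FALSE]

  target_ids <- match_target_drug(drug, target_names, role = role,
                                  substring = substring)

  # long event table: distinct (report, PT), SOC via the map
  ev <- unique(data.frame(primaryid = as.character(reac$primaryid),
                          pt = norm_key(reac$pt), stringsAsFactors = FALSE))
  ev <- ev[!is.na(ev$pt), , drop = FALSE]
  ev$soc <- map$soc[match(ev$pt, map$pt)]
  unmapped <- sort(unique(ev$pt[is.na(ev$soc)]))

  has_events <- ids %in% ev$primaryid
  if (any(!has_events))
    warning(sprintf("%d case(s) without any reaction dropped",
                    sum(!has_events)), call. = FALSE)
  demo <- demo[has_events, , drop = FALSE]
  ids <- as.character(demo$primaryid)
  ev <- ev[ev$primaryid %in% ids, , drop = FALSE]
  outc <- outc[as.character(outc$primaryid) %in% ids, , drop = FALSE]

  # earliest therapy start among target-drug rows with the analysis role
  tgt_norm <- norm_key(target_names)
  is_tgt_row <- norm_key(drug$role_cod) == norm_key(role) &
    (if (substring) {
       hit <- rep(FALSE, nrow(drug))
       for (nm in tgt_norm[!is.na(tgt_norm)])
         hit <- hit | grepl(nm, norm_key(drug$drugname), fixed = TRUE) |
           grepl(nm, norm_key(drug$prod_ai), fixed = TRUE)
       hit[is.na(hit)] <- FALSE
       hit
     } else {
       norm_key(drug$drugname) %in% tgt_norm |
         norm_key(drug$prod_ai) %in% tgt_norm
     })
  tdrug <- drug[is_tgt_row, c("primaryid", "drug_seq"), drop = FALSE]
  tther <- merge(
    data.frame(primaryid = as.character(tdrug$primaryid),
               dsg_drug_seq = tdrug$drug_seq),
    data.frame(primaryid = as.character(ther$primaryid),
               dsg_drug_seq = ther$dsg_drug_seq,
               start_dt = as.character(ther$start_dt)),
    by = c("primaryid", "dsg_drug_seq"))
  tther <- tther[!is.na(tther$start_dt), , drop = FALSE]
  start_map <- if (nrow(tther)) {
    agg <- stats::aggregate(list(key = pad_dt(tther$start_dt)),
                            by = list(primaryid = tther$primaryid), FUN = min)
    raw <- tther$start_dt[match(paste(agg$primaryid, agg$key),
                                paste(tther$primaryid, pad_dt(tther$start_dt)))]
    setNames(raw, agg$primaryid)
  } else setNames(character(0), character(0))

  cases <- data.frame(
    primaryid = ids,
    caseid = norm_key(demo$caseid),
    is_target = ids %in% target_ids,
    sex = demo$sex,
    age_years = age_to_years(demo$age, demo$age_cod),
    country = norm_key(demo$reporter_country),
    occp_cod = norm_key(demo$occp_cod),
    report_year = substr(as.character(demo[[year_field]]), 1, 4),
    fda_dt = as.character(demo$fda_dt),
    event_dt = as.character(demo$event_dt),
    target_start_dt = unname(start_map[ids]),
    stringsAsFactors = FALSE
  )
  rownames(cases) <- NULL

  manifest <- list(
    n_reports_total = n_total,
    n_after_dedup = n_dedup,
    n_target_ps = sum(cases$is_target),
    n_dropped_no_reaction = sum(!has_events),
    n_unmapped_pts = length(unmapped)
  )
  structure(list(
    cases = cases,
    events = ev[order(ev$primaryid, ev$pt), , drop = FALSE],
    outcomes = data.frame(primaryid = as.character(outc$primaryid),
                          outc_cod = as.character(outc$outc_cod),
                          stringsAsFactors = FALSE),
    manifest = manifest,
    unmapped = unmapped
  ), class = "analysis_cases")
}

#' @export
print.analysis_cases <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<analysis_cases: %d cases (%d target-PS), %d report-PT pairs, %d unmapped PTs>\n",
    nrow(x$cases), m$n_target_ps, nrow(x$events), m$n_unmapped_pts))
  invisible(x)
}
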