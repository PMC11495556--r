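## Reading and writing the FAERS quarterly ASCII dialect.
##
## The quarterly extracts ship five linked tables -- DEMO (demographic and
## administrative information), DRUG, REAC (MedDRA preferred terms), THER
## (therapy dates) and OUTC (outcomes) -- as dollar-delimited text with a
## header row.  Only the columns used by the analysis are required; real
## extracts carry many more, which are ignored.

FAERS_TABLES <- c("demo", "drug", "reac", "ther", "outc")

FAERS_COLUMNS <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
           "rept_dt", "age", "age_cod", "sex", "reporter_country", "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  outc = c("primaryid", "outc_cod")
)

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTC_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
AGE_UNITS  <- c("DEC", "YR", "MON", "WK", "DY", "HR")
SEX_CODES  <- c("M", "F", "UNK")

#' Parse FAERS date strings
#'
#' FAERS dates are digit strings of length 8 (`YYYYMMDD`), 6 (`YYYYMM`) or 4
#' (`YYYY`).  Partial dates keep their precision: the returned `date` is the
#' first day of the period and `precision` records how much of it is real.
#' Invalid calendar values (month 13, day 32) and non-digit input become
#' missing; a single warning reports how many values were dropped.
#'
#' @param raw character vector of digit strings ("" and `NA` allowed).
#' @return a data.frame with columns `date` (`Date`), `precision` (one of
#'   `"day"`, `"month"`, `"year"`, or `NA`) and `raw` (the canonical digit
#'   string, `NA` when unparseable).
#' @examples
#' parse_faers_date(c("20201215", "202012", "2020", "", "20209912"))
#' @export
parse_faers_date <- function(raw) {
  raw <- as.character(raw)
  raw[is.na(raw)] <- ""
  raw <- trimws(raw)
  n <- length(raw)
  date <- rep(as.Date(NA), n)
  precision <- rep(NA_character_, n)
  keep <- rep(NA_character_, n)

  digits <- grepl("^[0-9]*$", raw)
  bad <- !digits & raw != ""
  empty <- raw == ""

  yr <- mo <- dy <- rep(NA_integer_, n)
  len <- nchar(raw)
  ok <- digits & len %in% c(4L, 6L, 8L)
  bad <- bad | (digits & !empty & !len %in% c(4L, 6L, 8L))

  yr[ok] <- as.integer(substr(raw[ok], 1, 4))
  has_mo <- ok & len >= 6L
  mo[has_mo] <- as.integer(substr(raw[has_mo], 5, 6))
  has_dy <- ok & len == 8L
  dy[has_dy] <- as.integer(substr(raw[has_dy], 7, 8))

  # calendar validity; construct via as.Date so Feb 30 etc. are caught
  probe <- rep(NA, n)
  probe[ok] <- TRUE
  chk <- ok & ((has_mo & (mo < 1 | mo > 12)) | yr < 1900 | yr > 2100)
  probe[chk] <- FALSE
  idx <- which(ok & probe & has_dy)
  if (length(idx)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", yr[idx], mo[idx], dy[idx]),
                 format = "%Y-%m-%d")
    probe[idx[is.na(d)]] <- FALSE
    date[idx] <- d
    precision[idx] <- "day"
  }
  idx <- which(ok & probe & has_mo & !has_dy)
  if (length(idx)) {
    date[idx] <- as.Date(sprintf("%04d-%02d-01", yr[idx], mo[idx]))
    precision[idx] <- "month"
  }
  idx <- which(ok & probe & !has_mo)
  if (length(idx)) {
    date[idx] <- as.Date(sprintf("%04d-01-01", yr[idx]))
    precision[idx] <- "year"
  }
  bad <- bad | (ok & !probe)
  date[bad] <- NA
  precision[bad] <- NA_character_
  keep[!bad & !empty & ok] <- raw[!bad & !empty & ok]
  if (any(bad))
    warning(sprintf("%d unparseable date value(s) set to missing", sum(bad)),
            call. = FALSE)
  data.frame(date = date, precision = precision, raw = keep,
             stringsAsFactors = FALSE)
}

#' Convert FAERS age values to years
#'
#' Units follow the FAERS `age_cod` vocabulary: `DEC` decades, `YR` years,
#' `MON` months, `WK` weeks, `DY` days, `HR` hours.  A missing unit with a
#' non-missing value is treated as years (FAERS practice) with a warning.
#'
#' @param value numeric vector of ages (`>= 0`).
#' @param unit character vector of unit codes, recycled if length 1.
#' @return numeric vector of ages in years; `NA` where value is missing or
#'   the unit code is unknown.
#' @examples
#' age_to_years(c(7.5, 18, 365.25), c("DEC", "MON", "DY"))
#' @export
age_to_years <- function(value, unit) {
  value <- as.numeric(value)
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  unit <- norm_key(unit)
  factor_for <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
                  DY = 1 / 365.25, HR = 1 / 8766)
  no_unit <- is.na(unit) & !is.na(value)
  if (any(no_unit)) {
    warning(sprintf("%d age value(s) with missing unit treated as years",
                    sum(no_unit)), call. = FALSE)
    unit[no_unit] <- "YR"
  }
  unknown <- !is.na(unit) & !unit %in% names(factor_for)
  if (any(unknown)) {
    warning(sprintf("%d unknown age unit(s) set to missing", sum(unknown)),
            call. = FALSE)
    unit[unknown] <- NA_character_
  }
  out <- value * unname(factor_for[unit])
  out[is.na(unit)] <- NA_real_
  out
}

# validate a vector of raw date strings, returning the canonical string or NA
# (count of invalid values is attached as an attribute)
clean_dt <- function(x) {
  p <- suppressWarnings(parse_faers_date(x))
  n_bad <- sum(!is.na(x) & trimws(as.character(x)) != "" & is.na(p$raw))
  structure(p$raw, n_bad = n_bad)
}

#' Construct a FAERS case-record bundle
#'
#' Bundles the five per-quarter tables into one object and enforces the
#' linkage invariants: unique `primaryid` in DEMO, and every child-table
#' `primaryid` present in DEMO.  Violating rows are dropped and counted in
#' the bundle's `log`.
#'
#' @param demo,drug,reac,ther,outc data.frames with (at least) the columns in
#'   `faersignal:::FAERS_COLUMNS`.
#' @param quarter_label string such as `"2020Q4"`.
#' @param log list of ingestion counters (used by [read_quarter_tables()]).
#' @return an object of class `faers_bundle`.
#' @export
faers_bundle <- function(demo, drug, reac, ther, outc,
                         quarter_label = "SYN", log = list()) {
  canon <- function(df) {
    # canonical field form: whitespace-trimmed, "" as NA (case preserved);
    # guarantees read(write(bundle)) == bundle
    df <- as.data.frame(df)
    for (nm in names(df)) {
      if (is.character(df[[nm]])) {
        v <- trimws(df[[nm]])
        v[!is.na(v) & v == ""] <- NA_character_
        df[[nm]] <- v
      }
    }
    df
  }
  demo <- canon(demo); drug <- canon(drug)
  reac <- canon(reac); ther <- canon(ther)
  outc <- canon(outc)
  for (tab in FAERS_TABLES) {
    df <- get(tab)
    missing_cols <- setdiff(FAERS_COLUMNS[[tab]], names(df))
    if (length(missing_cols))
      data_error(sprintf("table '%s' lacks required column(s): %s",
                         tab, paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(norm_key(demo$primaryid))
  if (any(dup)) {
    log$demo_duplicate_primaryid <- sum(dup)
    demo <- demo[!dup, , drop = FALSE]
  }
  ids <- norm_key(demo$primaryid)
  drop_orphans <- function(df, nm) {
    orphan <- !norm_key(df$primaryid) %in% ids
    if (any(orphan)) log[[paste0(nm, "_orphan")]] <<- sum(orphan)
    df[!orphan, , drop = FALSE]
  }
  drug <- drop_orphans(drug, "drug")
  reac <- drop_orphans(reac, "reac")
  ther <- drop_orphans(ther, "ther")
  outc <- drop_orphans(outc, "outc")
  structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc, quarter_label = quarter_label, log = log),
            class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat(sprintf(
    "<faers_bundle %s: %d reports, %d drug rows, %d reactions, %d therapy rows, %d outcomes>\n",
    x$quarter_label, nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$ther),
    nrow(x$outc)))
  invisible(x)
}

# split one raw file into validated records for table `tab`.
# Returns list(records = data.frame, malformed = int, rejected = int,
#              bad_dates = int, bad_age = int)
parse_faers_file <- function(path, tab, sep = "$") {
  if (!file.exists(path)) data_error(sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) data_error(sprintf("empty file: %s", path))
  header <- tolower(trimws(strsplit(lines[[1]], sep, fixed = TRUE)[[1]]))
  required <- FAERS_COLUMNS[[tab]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    data_error(sprintf("file '%s' lacks required column(s): %s",
                       path, paste(missing_cols, collapse = ", ")))
  body <- lines[-1]
  body <- body[trimws(body) != ""]
  out <- list(malformed = 0L, rejected = 0L, bad_dates = 0L, bad_age = 0L)
  if (!length(body)) {
    rec <- as.data.frame(setNames(rep(list(character(0)), length(required)),
                                  required))
    out$records <- rec
    return(out)
  }
  parts <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty field is dropped by strsplit; tolerate one-short rows
  ok <- nf >= length(header) - 1L & nf <= length(header)
  out$malformed <- sum(!ok)
  parts <- parts[ok]
  if (!length(parts)) {
    rec <- as.data.frame(setNames(rep(list(character(0)), length(required)),
                                  required))
    out$records <- rec
    return(out)
  }
  cols <- data.table::transpose(parts)   # C-level list-of-rows -> columns
  if (length(cols) < length(header))
    cols <- c(cols, rep(list(rep(NA_character_, length(parts))),
                        length(header) - length(cols)))
  names(cols) <- header
  df <- as.data.frame(cols[required], stringsAsFactors = FALSE,
                      check.names = FALSE)
  for (nm in names(df)) {
    df[[nm]] <- trimws(df[[nm]])
    df[[nm]][df[[nm]] == ""] <- NA_character_
  }
  keep <- rep(TRUE, nrow(df))
  if (tab == "demo") {
    keep <- !is.na(df$primaryid) & !is.na(df$caseid)
    df$caseversion <- suppressWarnings(as.integer(df$caseversion))
    for (f in c("fda_dt", "event_dt", "rept_dt")) {
      cl <- clean_dt(df[[f]])
      out$bad_dates <- out$bad_dates + attr(cl, "n_bad")
      df[[f]] <- as.character(cl)
    }
    age_num <- suppressWarnings(as.numeric(df$age))
    out$bad_age <- sum(!is.na(df$age) & is.na(age_num)) +
      sum(!is.na(age_num) & age_num < 0)
    age_num[!is.na(age_num) & age_num < 0] <- NA_real_
    df$age <- age_num
    df$age_cod <- norm_key(df$age_cod)
    df$age_cod[!df$age_cod %in% AGE_UNITS] <- NA_character_
    df$sex <- norm_key(df$sex)
    df$sex[!df$sex %in% SEX_CODES] <- NA_character_
    df$occp_cod <- norm_key(df$occp_cod)
  } else if (tab == "drug") {
    df$role_cod <- norm_key(df$role_cod)
    df$drug_seq <- suppressWarnings(as.integer(df$drug_seq))
    keep <- !is.na(df$primaryid) & df$role_cod %in% ROLE_CODES &
      !is.na(df$drug_seq) & df$drug_seq >= 1L
  } else if (tab == "reac") {
    keep <- !is.na(df$primaryid) & !is.na(df$pt)
  } else if (tab == "ther") {
    df$dsg_drug_seq <- suppressWarnings(as.integer(df$dsg_drug_seq))
    keep <- !is.na(df$primaryid) & !is.na(df$dsg_drug_seq)
    for (f in c("start_dt", "end_dt")) {
      cl <- clean_dt(df[[f]])
      out$bad_dates <- out$bad_dates + attr(cl, "n_bad")
      df[[f]] <- as.character(cl)
    }
  } else if (tab == "outc") {
    df$outc_cod <- norm_key(df$outc_cod)
    keep <- !is.na(df$primaryid) & df$outc_cod %in% OUTC_CODES
  }
  out$rejected <- sum(!keep)
  out$records <- df[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Read the five FAERS quarterly tables
#'
#' Parses the dollar-delimited ASCII dialect.  A missing required column is a
#' fatal error naming the file and the column; malformed lines and records
#' violating an enum (e.g. a drug `role_cod` outside PS/SS/C/I) are counted
#' in the returned bundle's `log`, never silently dropped.  Unreadable dates
#' and ages are kept as records with the field set to missing.
#'
#' @param paths named list/vector with elements `demo`, `drug`, `reac`,
#'   `ther`, `outc` giving the file path of each table.
#' @param quarter_label label stored on the bundle, e.g. `"2020Q4"`.
#' @param sep field delimiter, default `"$"` (the FAERS quarterly dialect).
#' @return a [faers_bundle()] whose `log` holds per-table `malformed`,
#'   `rejected`, `bad_dates` and `bad_age` counters.
#' @seealso [write_quarter_tables()]
#' @export
read_quarter_tables <- function(paths, quarter_label = "unknown", sep = "$") {
  paths <- as.list(paths)
  missing_tabs <- setdiff(FAERS_TABLES, names(paths))
  if (length(missing_tabs))
    config_error(sprintf("paths must name the five tables; missing: %s",
                         paste(missing_tabs, collapse = ", ")))
  parsed <- lapply(FAERS_TABLES, function(tab)
    parse_faers_file(paths[[tab]], tab, sep = sep))
  names(parsed) <- FAERS_TABLES
  log <- lapply(parsed, function(p) p[setdiff(names(p), "records")])
  faers_bundle(parsed$demo$records, parsed$drug$records, parsed$reac$records,
               parsed$ther$records, parsed$outc$records,
               quarter_label = quarter_label, log = log)
}

#' Write a bundle back to the FAERS ASCII dialect
#'
#' Emits the five dollar-delimited files that [read_quarter_tables()]
#' accepts; dates are serialised at their stored precision and missing
#' fields as empty strings, so write -> read -> write is byte-identical.
#'
#' @param bundle a [faers_bundle()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix, default `"syn"`.
#' @return named character vector of the five file paths.
#' @export
write_quarter_tables <- function(bundle, dir, prefix = "syn") {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) data_error(sprintf("cannot create directory: %s", dir))
  paths <- character(0)
  for (tab in FAERS_TABLES) {
    df <- bundle[[tab]][, FAERS_COLUMNS[[tab]], drop = FALSE]
    path <- file.path(dir, sprintf("%s_%s.txt", prefix, toupper(tab)))
    dt <- data.table::as.data.table(df)
    data.table::fwrite(dt, path, sep = "$", quote = FALSE, na = "",
                       eol = "\n", scipen = 50)
    paths[[tab]] <- path
  }
  paths
}
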