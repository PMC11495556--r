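## Clinical-characteristics summary of the target cohort: gender, age bins,
## reporter type, top countries, reporting year, one serious outcome per case.

AGE_BIN_LEVELS <- c("<18", "18~64", "65~85", ">85", "Unknown")

OUTCOME_PRECEDENCE <- c("DE", "LT", "DS", "CA", "RI", "HO", "OT")

OUTCOME_LABELS <- c(
  DE = "Death",
  LT = "Life-Threatening",
  HO = "Hospitalization (initial or prolonged)",
  DS = "Disability",
  CA = "Congenital Anomaly",
  RI = "Required Intervention to Prevent Permanent",
  OT = "Other Serious (Important Medical Event)"
)

OCCP_LABELS <- c(
  MD = "Physician",
  PH = "Pharmacist",
  CN = "Consumer",
  HP = "Health Professional",
  OT = "Health Professional"
)

#' Bin an age in years into the reporting age groups
#'
#' Bins are `<18`, `18~64`, `65~85` (85 inclusive), `>85`, `Unknown`.
#' Ages are rounded to the nearest integer before binning, so 64.6 falls in
#' `65~85`.  Missing and negative ages go to `Unknown` (negative with a
#' warning).
#'
#' @param age_years numeric vector of ages in years.
#' @return character vector of bin labels.
#' @export
bin_age <- function(age_years) {
  age_years <- as.numeric(age_years)
  neg <- !is.na(age_years) & age_years < 0
  if (any(neg)) {
    warning(sprintf("%d negative age(s) binned as Unknown", sum(neg)),
            call. = FALSE)
    age_years[neg] <- NA_real_
  }
  a <- round(age_years)
  out <- rep("Unknown", length(a))
  out[!is.na(a) & a < 18] <- "<18"
  out[!is.na(a) & a >= 18 & a <= 64] <- "18~64"
  out[!is.na(a) & a >= 65 & a <= 85] <- "65~85"
  out[!is.na(a) & a > 85] <- ">85"
  out
}

#' Collapse a case's outcome codes to a single serious-outcome level
#'
#' A case can carry several outcome codes; the characteristics table needs
#' one row per case, so the highest-precedence code wins.  The default
#' precedence is severity-ordered: `DE > LT > DS > CA > RI > HO > OT`.
#'
#' @param outcomes character vector of `outc_cod` values for ONE case (may
#'   be empty).
#' @param precedence code order, first wins.
#' @return the label of the selected outcome, or `"Unknown"` for an empty
#'   set.  Unknown codes are ignored with a warning.
#' @export
assign_primary_outcome <- function(outcomes, precedence = OUTCOME_PRECEDENCE) {
  outcomes <- norm_key(outcomes)
  outcomes <- outcomes[!is.na(outcomes)]
  bad <- setdiff(outcomes, names(OUTCOME_LABELS))
  if (length(bad)) {
    warning(sprintf("ignoring unknown outcome code(s): %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
    outcomes <- setdiff(outcomes, bad)
  }
  hit <- precedence[precedence %in% outcomes]
  if (!length(hit)) return("Unknown")
  unname(OUTCOME_LABELS[hit[[1]]])
}

# vectorised form used by summarize_characteristics: outcomes long table ->
# named vector primaryid -> label
primary_outcome_by_case <- function(outcomes, precedence = OUTCOME_PRECEDENCE) {
  if (!NROW(outcomes)) return(setNames(character(0), character(0)))
  oc <- norm_key(outcomes$outc_cod)
  rank <- match(oc, precedence)
  ok <- !is.na(rank)
  dt <- data.table::data.table(primaryid = as.character(outcomes$primaryid)[ok],
                               rank = rank[ok])
  best <- dt[, list(rank = min(rank)), by = "primaryid"]
  setNames(unname(OUTCOME_LABELS[precedence[best$rank]]), best$primaryid)
}

#' Summarise clinical characteristics of the target cohort
#'
#' Builds the per-category count/percent table for target (primary-suspect)
#' cases: gender, age bins, reporter type, reporting countries (top N, the
#' remainder pooled as `Other`), reporting year, and one serious outcome per
#' case.  Within each category the counts sum to the cohort size; `Unknown`
#' levels absorb missing values.  Percentages are of the cohort total,
#' rounded to 2 decimals.
#'
#' @param acases an `analysis_cases` object from [assemble_case_table()],
#'   or a data.frame shaped like its `cases` component (then `outcomes`
#'   may be supplied separately).
#' @param top_n_countries how many countries to list individually.
#' @param outcomes optional long outcomes table when `acases` is a plain
#'   data.frame.
#' @return data.frame of class `characteristics_table` with columns
#'   `category`, `level`, `count`, `percent`.
#' @export
summarize_characteristics <- function(acases, top_n_countries = 5,
                                      outcomes = NULL) {
  if (inherits(acases, "analysis_cases")) {
    cases <- acases$cases[acases$cases$is_target, , drop = FALSE]
    outcomes <- acases$outcomes
  } else {
    cases <- as.data.frame(acases)
    if (!is.null(cases$is_target)) cases <- cases[cases$is_target, ,
                                                  drop = FALSE]
  }
  n <- nrow(cases)
  if (!n) data_error("summarize_characteristics: no target cases")

  block <- function(category, levels_vec, order_levels = NULL) {
    levels_vec[is.na(levels_vec)] <- "Unknown"
    tab <- table(levels_vec)
    lv <- if (is.null(order_levels)) {
      c(sort(setdiff(names(tab), "Unknown")), intersect("Unknown", names(tab)))
    } else intersect(order_levels, names(tab))
    data.frame(category = category, level = lv,
               count = as.integer(tab[lv]),
               percent = round(100 * as.integer(tab[lv]) / n, 2),
               stringsAsFactors = FALSE)
  }

  sex_lab <- c(M = "Male", F = "Female", UNK = "Unknown")[cases$sex]
  g <- block("Gender", unname(sex_lab),
             c("Female", "Male", "Unknown"))

  a <- block("Age (year)", bin_age(cases$age_years), AGE_BIN_LEVELS)

  rep_lab <- unname(OCCP_LABELS[cases$occp_cod])
  r <- block("Reported Person", rep_lab,
             c("Consumer", "Health Professional", "Physician", "Pharmacist",
               "Unknown"))

  ctry <- cases$country
  ctry[is.na(ctry)] <- "Unknown"
  ctab <- sort(table(ctry[ctry != "Unknown"]), decreasing = TRUE)
  top <- head(names(ctab), top_n_countries)
  ctry2 <- ifelse(ctry %in% top, ctry, ifelse(ctry == "Unknown",
                                              "Unknown", "Other"))
  co <- block("Reported Countries", ctry2, c(top, "Other", "Unknown"))

  yr <- cases$report_year
  yr[is.na(yr) | yr == ""] <- "Unknown"
  y <- block("Reporting year", yr)

  oc_map <- primary_outcome_by_case(outcomes)
  oc_lab <- unname(oc_map[cases$primaryid])
  o <- block("Serious outcome", oc_lab,
             c(unname(OUTCOME_LABELS[OUTCOME_PRECEDENCE]), "Unknown"))

  out <- rbind(g, a, r, co, y, o)
  rownames(out) <- NULL
  attr(out, "n_cases") <- n
  class(out) <- c("characteristics_table", "data.frame")
  out
}
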