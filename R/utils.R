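#' @importFrom stats median qnorm rbinom rgamma rlnorm rnorm rpois runif setNames quantile
#' @importFrom utils head modifyList
#' @importFrom data.table data.table as.data.table setorder fwrite transpose
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table non-standard-evaluation columns
utils::globalVariables(c("is_target", "caseid", "fda_key", "pid_num",
                         "primaryid", "rank"))

#' Normalise a text key FAERS-style
#'
#' FAERS files mix upper/lower case and stray whitespace; all key comparisons
#' in this package (drug names, PTs, SOCs, case ids) go through this.
#'
#' @param x character vector.
#' @return trimmed, upper-cased character vector (`NA` preserved).
#' @export
norm_key <- function(x) {
  out <- toupper(trimws(as.character(x)))
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

# Pad a partial date string (YYYY / YYYYMM / YYYYMMDD) to 8 chars so that
# lexicographic order equals chronological order with partial dates sorting
# before any full date of the same period.  Missing -> "00000000" (earliest).
pad_dt <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  formatC(x, width = 8, flag = "-", format = "s") |>
    gsub(pattern = " ", replacement = "0")
}

# Internal condition helpers: the CLI maps these classes onto exit codes.
config_error <- function(msg) {
  stop(structure(class = c("faers_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
data_error <- function(msg) {
  stop(structure(class = c("faers_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
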