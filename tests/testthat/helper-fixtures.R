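# Hand fixtures used across test files.  Everything is built in code; the
# expected numbers were enumerated by hand before the implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 2-SOC / 3-PT map shared by the fixtures
fixture_map <- function() {
  meddra_map(c("P1", "P2", "P3"), c("S1", "S1", "S2"))
}

empty_df <- function(cols) {
  as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
}

# Five distinct reports for contingency enumeration:
#   R1: drug X (PS), PTs {P1, P2}
#   R2: drug X (PS), PT  {P1}
#   R3: drug Y (PS), PT  {P1}
#   R4: drug Y (PS), PT  {P2}
#   R5: drug Y (PS), PT  {P3}
fixture_bundle_contingency <- function() {
  demo <- data.frame(
    primaryid = c("11", "21", "31", "41", "51"),
    caseid = c("1", "2", "3", "4", "5"),
    caseversion = 1L,
    fda_dt = "20210301", event_dt = NA_character_, rept_dt = "20210301",
    age = NA_real_, age_cod = NA_character_, sex = "M",
    reporter_country = "US", occp_cod = "CN", stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = demo$primaryid, drug_seq = 1L, role_cod = "PS",
    drugname = c("X", "X", "Y", "Y", "Y"),
    prod_ai = NA_character_, stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("11", "11", "21", "31", "41", "51"),
    pt = c("P1", "P2", "P1", "P1", "P2", "P3"), stringsAsFactors = FALSE)
  faers_bundle(demo, drug, reac,
               empty_df(c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")),
               empty_df(c("primaryid", "outc_cod")),
               quarter_label = "FIX")
}

fixture_acases_contingency <- function() {
  assemble_case_table(fixture_bundle_contingency(), "X", fixture_map())
}

# Five reports for flow accounting: case C1 has two versions (non-target),
# C2 and C3 are target-PS, C4 is non-target.
# Expected manifest: reports 5, after dedup 4, target-PS 2.
fixture_bundle_flow <- function() {
  demo <- data.frame(
    primaryid = c("101", "102", "201", "301", "401"),
    caseid = c("C1", "C1", "C2", "C3", "C4"),
    caseversion = c(1L, 2L, 1L, 1L, 1L),
    fda_dt = c("20210101", "20210301", "20210201", "20210202", "20210203"),
    event_dt = c(NA, NA, "20210110", "20210115", NA),
    rept_dt = "20210301",
    age = c(70, 70, 80, NA, 55), age_cod = "YR",
    sex = c("M", "M", "M", "F", NA),
    reporter_country = c("US", "US", "US", "JP", "US"),
    occp_cod = c("CN", "CN", "MD", NA, "CN"), stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("101", "102", "201", "301", "401"),
    drug_seq = 1L, role_cod = "PS",
    drugname = c("OTHERDRUG", "OTHERDRUG", "ORGOVYX", "relugolix ", "DECOY"),
    prod_ai = c(NA, NA, "RELUGOLIX", NA, NA), stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("101", "102", "201", "201", "301", "401"),
    pt = c("P3", "P3", "P1", "P2", "P1", "P2"), stringsAsFactors = FALSE)
  ther <- data.frame(
    primaryid = c("201", "301"), dsg_drug_seq = 1L,
    start_dt = c("20210101", "20210101"), end_dt = NA_character_,
    stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = c("201", "201", "301"),
                     outc_cod = c("HO", "DE", "OT"), stringsAsFactors = FALSE)
  faers_bundle(demo, drug, reac, ther, outc, quarter_label = "FIX")
}

fixture_acases_flow <- function() {
  assemble_case_table(fixture_bundle_flow(), c("RELUGOLIX", "ORGOVYX"),
                      fixture_map())
}

# Scalar brute-force oracle for the four algorithms, written directly from
# the printed formulas and kept loop-based and independent of the package's
# vectorised implementation.
oracle_stats_scalar <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  prr <- (a * (c + d)) / (c * (a + b))
  chi2 <- ((a * d - b * c)^2 * N) / ((a + b) * (c + d) * (a + c) * (b + d))
  ebgm <- (a * N) / ((a + b) * (a + c))
  ic <- log2(ebgm)
  a1 <- 1; b1 <- 1; g11 <- 1; al <- 2; be <- 2
  g <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  V <- (1 / log(2))^2 * (
    (N - a + g - g11) / ((a + g11) * (1 + N + g)) +
    (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
    (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be)))
  list(ror = ror,
       ror_lo = exp(log(ror) - 1.96 * se), ror_hi = exp(log(ror) + 1.96 * se),
       prr = prr, chi2 = chi2, ic = ic, ic025 = ic - 2 * sqrt(V),
       ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se),
       pass_ror = (exp(log(ror) - 1.96 * se) > 1) && a >= 3,
       pass_prr = (prr >= 2) && (chi2 >= 4) && a >= 3,
       pass_bcpnn = (ic - 2 * sqrt(V)) > 0,
       pass_mgps = exp(log(ebgm) - 1.96 * se) > 2)
}
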