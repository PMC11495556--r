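test_that("parse_faers_date handles the three precisions, blanks and junk", {
  p <- parse_faers_date(c("20201215", "202012", "2020", "", NA))
  expect_equal(p$date,
               as.Date(c("2020-12-15", "2020-12-01", "2020-01-01", NA, NA)))
  expect_equal(p$precision, c("day", "month", "year", NA, NA))
  expect_equal(p$raw, c("20201215", "202012", "2020", NA, NA))

  expect_warning(bad <- parse_faers_date(c("20209912", "20210232", "12ab",
                                           "202", "20210101")),
                 "unparseable")
  expect_equal(is.na(bad$date), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(bad$precision[5], "day")
})

test_that("age_to_years applies the documented unit conversions", {
  expect_equal(age_to_years(7.5, "DEC"), 75)
  expect_equal(age_to_years(18, "MON"), 1.5)
  expect_equal(age_to_years(365.25, "DY"), 1)
  expect_equal(age_to_years(c(2, 14), c("YR", "WK")), c(2, 14 * 7 / 365.25))
  expect_equal(age_to_years(8766, "HR"), 1)
  expect_warning(y <- age_to_years(50, NA), "missing unit")
  expect_equal(y, 50)
  expect_warning(y2 <- age_to_years(50, "XX"), "unknown age unit")
  expect_true(is.na(y2))
})

test_that("read_quarter_tables parses, rejects enum violations and counts drops", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$caseversion$fda_dt$event_dt$rept_dt$age$age_cod$sex$reporter_country$occp_cod",
               "11$1$1$20210101$20201215$20210101$70$YR$M$US$CN",
               "21$2$1$20210102$$20210102$$$F$JP$MD"),
             file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname$prod_ai",
               "11$1$PS$ORGOVYX$RELUGOLIX",
               "21$1$PS$DECOY$",
               "21$2$XX$BROKEN$",       # bad role code -> rejected
               "99$1$PS$ORPHAN$"),      # unknown primaryid -> orphan
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "11$Hot flush", "21$Fatigue", "21$"),
             file.path(dir, "REAC.txt"))
  writeLines(c("primaryid$dsg_drug_seq$start_dt$end_dt", "11$1$20201201$"),
             file.path(dir, "THER.txt"))
  writeLines(c("primaryid$outc_cod", "11$HO", "21$ZZ"),
             file.path(dir, "OUTC.txt"))
  paths <- list(demo = file.path(dir, "DEMO.txt"),
                drug = file.path(dir, "DRUG.txt"),
                reac = file.path(dir, "REAC.txt"),
                ther = file.path(dir, "THER.txt"),
                outc = file.path(dir, "OUTC.txt"))
  b <- read_quarter_tables(paths, quarter_label = "2021Q1")
  expect_s3_class(b, "faers_bundle")
  expect_equal(nrow(b$demo), 2)
  expect_equal(b$demo$age, c(70, NA))
  expect_equal(nrow(b$drug), 2)          # XX rejected, orphan dropped
  expect_equal(b$log$drug$rejected, 1)
  expect_equal(b$log$drug$drug_orphan %||% b$log$drug_orphan, 1)
  expect_equal(nrow(b$reac), 2)          # empty PT rejected
  expect_equal(b$log$reac$rejected, 1)
  expect_equal(b$log$outc$rejected, 1)   # unknown outcome code
  # records + rejections account for every data line (drug table: 4 lines)
  expect_equal(nrow(b$drug) + b$log$drug$rejected +
                 (b$log$drug_orphan %||% 0) + b$log$drug$malformed, 4)
})

test_that("a missing required column is fatal and names file and column", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid", "11$1"), file.path(dir, "DEMO.txt"))
  for (t in c("DRUG", "REAC", "THER", "OUTC"))
    writeLines("x", file.path(dir, paste0(t, ".txt")))
  paths <- list(demo = file.path(dir, "DEMO.txt"),
                drug = file.path(dir, "DRUG.txt"),
                reac = file.path(dir, "REAC.txt"),
                ther = file.path(dir, "THER.txt"),
                outc = file.path(dir, "OUTC.txt"))
  expect_error(read_quarter_tables(paths), "fda_dt",
               class = "faers_data_error")
})

test_that("write -> read round-trips a bundle, and write is idempotent", {
  b <- fixture_bundle_flow()
  dir <- withr::local_tempdir()
  paths <- write_quarter_tables(b, dir)
  b2 <- read_quarter_tables(as.list(paths), quarter_label = b$quarter_label)
  for (tab in c("demo", "drug", "reac", "ther", "outc")) {
    expect_equal(b2[[tab]], b[[tab]], ignore_attr = TRUE,
                 label = paste("table", tab))
  }
  dir2 <- withr::local_tempdir()
  paths2 <- write_quarter_tables(b2, dir2)
  for (tab in names(paths)) {
    expect_identical(readLines(paths[[tab]]), readLines(paths2[[tab]]),
                     label = paste("byte identity", tab))
  }
})

test_that("an empty bundle writes five header-only files", {
  b <- faers_bundle(
    empty_df(c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
               "rept_dt", "age", "age_cod", "sex", "reporter_country",
               "occp_cod")),
    empty_df(c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai")),
    empty_df(c("primaryid", "pt")),
    empty_df(c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")),
    empty_df(c("primaryid", "outc_cod")))
  dir <- withr::local_tempdir()
  paths <- write_quarter_tables(b, dir)
  for (pp in paths) expect_length(readLines(pp), 1L)
})
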