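test_that("deduplicate_cases keeps latest fda_dt, breaks ties by primaryid", {
  demo <- data.frame(primaryid = c("100010", "100012", "200011", "300011"),
                     caseid = c("C1", "C1", "C2", "C3"),
                     fda_dt = c("20210101", "20210301", "20210101", NA))
  keep <- deduplicate_cases(demo)
  expect_setequal(keep, c("100012", "200011", "300011"))
  expect_equal(attr(keep, "removed"), 1L)

  # equal dates: numerically largest primaryid wins
  demo2 <- data.frame(primaryid = c("100010", "100012"),
                      caseid = "C1", fda_dt = "20210101")
  expect_equal(as.character(deduplicate_cases(demo2)), "100012")

  # missing fda_dt always loses against any dated version
  demo3 <- data.frame(primaryid = c("900", "7"), caseid = "C1",
                      fda_dt = c(NA, "19990101"))
  expect_equal(as.character(deduplicate_cases(demo3)), "7")
})

test_that("deduplication is idempotent, order-independent, one per caseid", {
  set.seed(11)
  n_cases <- 40
  demo <- data.frame(
    primaryid = as.character(sample(1e5, 100)),
    caseid = sample(paste0("C", seq_len(n_cases)), 100, replace = TRUE),
    fda_dt = format(as.Date("2021-01-01") + sample(0:400, 100, TRUE),
                    "%Y%m%d"))
  keep <- deduplicate_cases(demo)
  expect_length(keep, length(unique(demo$caseid)))
  # permutation invariance
  for (i in 1:5) {
    perm <- demo[sample(nrow(demo)), ]
    expect_equal(as.character(deduplicate_cases(perm)), as.character(keep))
  }
  # idempotence: dedup of the retained set keeps everything
  demo_kept <- demo[demo$primaryid %in% keep, ]
  expect_setequal(as.character(deduplicate_cases(demo_kept)),
                  as.character(keep))
})

test_that("match_target_drug honours role filter and normalisation", {
  drug <- data.frame(
    primaryid = c("1", "2", "3", "4"),
    drug_seq = 1L,
    role_cod = c("PS", "C", "PS", "PS"),
    drugname = c("ORGOVYX", "RELUGOLIX", "other", "RELUGOLIX COMBO"),
    prod_ai = c(NA, NA, "relugolix ", NA))
  hits <- match_target_drug(drug, c("RELUGOLIX", "ORGOVYX"))
  expect_setequal(hits, c("1", "3"))   # role C excluded; trailing space ok
  # substring mode additionally catches the combination product
  expect_setequal(match_target_drug(drug, "RELUGOLIX", substring = TRUE),
                  c("3", "4"))
  expect_error(match_target_drug(drug, character(0)),
               class = "faers_config_error")
})

test_that("standardize_terms maps PTs and reports unmapped ones", {
  map <- meddra_map("Hot flush", "Vascular disorders")
  r1 <- standardize_terms("Hot flush", map)
  expect_equal(r1$socs, "Vascular disorders")
  expect_length(r1$unmapped, 0)
  r2 <- standardize_terms(c("Hot flush", "Qwertyitis"), map)
  expect_equal(r2$unmapped, "QWERTYITIS")
  expect_equal(r2$socs, "Vascular disorders")
  expect_error(meddra_map(c("P1", "P1"), c("S1", "S2")),
               class = "faers_data_error")
})

test_that("assemble_case_table reproduces the hand-enumerated flow manifest", {
  ac <- fixture_acases_flow()
  expect_equal(ac$manifest$n_reports_total, 5)
  expect_equal(ac$manifest$n_after_dedup, 4)
  expect_equal(ac$manifest$n_target_ps, 2)
  expect_setequal(ac$cases$primaryid[ac$cases$is_target], c("201", "301"))
  # the retained version of C1 is the later one
  expect_true("102" %in% ac$cases$primaryid)
  expect_false("101" %in% ac$cases$primaryid)
  # SOC always has a PT preimage
  expect_true(all(ac$events$soc[!is.na(ac$events$soc)] %in%
                    fixture_map()$soc))
  # therapy start date attached to target cases
  expect_equal(ac$cases$target_start_dt[ac$cases$primaryid == "201"],
               "20210101")
})

test_that("assemble is idempotent and tolerates zero target matches", {
  b <- fixture_bundle_flow()
  map <- fixture_map()
  a1 <- assemble_case_table(b, c("RELUGOLIX", "ORGOVYX"), map)
  a2 <- assemble_case_table(b, c("RELUGOLIX", "ORGOVYX"), map)
  expect_identical(a1$cases, a2$cases)
  expect_identical(a1$events, a2$events)

  a0 <- assemble_case_table(b, "NOSUCHDRUG", map)
  expect_equal(a0$manifest$n_target_ps, 0)
  expect_equal(a0$manifest$n_after_dedup, 4)
})
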