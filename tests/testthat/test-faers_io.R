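test_that("read_reports parses both dialects and rejects malformed rows", {
  p <- write_report_csv(c("R1,Tylenol,primary_suspect,Hepatitis,2004Q1",
                          "R2,Aspirin,other,Nausea,2004Q2",
                          "R3,Tylenol,primary_suspect,Jaundice,2005Q1"))
  recs <- read_reports(p, "simple_csv")
  expect_equal(nrow(recs), 3)
  expect_equal(attr(recs, "n_rejected"), 0)
  expect_true(all(is.na(recs$event_soc)))

  # one row missing its event term is counted, not silently dropped
  p2 <- write_report_csv(c("R1,Tylenol,primary_suspect,Hepatitis,2004Q1",
                           "R2,Aspirin,primary_suspect,,2004Q2",
                           "R3,Advil,other,Rash,2004Q3"))
  expect_message(recs2 <- read_reports(p2, "simple_csv"), "rejected 1")
  expect_equal(nrow(recs2), 2)
  expect_equal(attr(recs2, "n_rejected"), 1)

  # header-only file -> empty collection
  p3 <- write_report_csv(character())
  expect_equal(nrow(read_reports(p3, "simple_csv")), 0)

  # FAERS-style dollar-separated dialect; PS maps to primary_suspect
  p4 <- tempfile(fileext = ".txt")
  writeLines(c("primaryid$drugname$role_cod$pt$quarter",
               "1001$TYLENOL$PS$Hepatitis$2004Q1",
               "1002$ASPIRIN$SS$Nausea$2004Q1"), p4)
  recs4 <- read_reports(p4, "faers_dollar")
  expect_equal(recs4$role, c("primary_suspect", "other"))
  expect_equal(recs4$report_id, c("1001", "1002"))

  expect_error(read_reports(tempfile(), "simple_csv"), "cannot read")
})

test_that("filter_primary_suspect keeps exactly the PS records, idempotently", {
  recs <- toy_records(data.frame(drug = c("d1", "d2", "d3"),
                                 event = c("e1", "e1", "e2")))
  recs$role <- c("primary_suspect", "other", "primary_suspect")
  out <- filter_primary_suspect(recs)
  expect_equal(out$drug, c("d1", "d3"))
  expect_equal(filter_primary_suspect(out), out)  # idempotent
  recs$role <- "other"
  expect_equal(nrow(filter_primary_suspect(recs)), 0)
})

test_that("normalize_drug_names matches exactly after case/space folding", {
  syn <- data.frame(raw_name = c("tylenol", "advil"),
                    canonical_id = c("acetaminophen", "ibuprofen"))
  recs <- toy_records(data.frame(drug = c("TYLENOL ", "tylenol 500mg",
                                          "Advil"),
                                 event = "e1"))
  recs$drug_name_raw <- recs$drug
  res <- suppressMessages(normalize_drug_names(recs, syn))
  expect_equal(res$matched$drug, c("acetaminophen", "ibuprofen"))
  # freestyle name with dose text must NOT fuzzy-match
  expect_equal(res$unmatched$drug_name_raw, "tylenol 500mg")

  empty <- suppressMessages(
    normalize_drug_names(recs, data.frame(raw_name = character(),
                                          canonical_id = character())))
  expect_equal(nrow(empty$matched), 0)
  expect_equal(nrow(empty$unmatched), 3)

  expect_error(normalize_drug_names(
    recs, data.frame(raw_name = c("a", "A "), canonical_id = c("x", "y"))),
    "unique")
})

test_that("map_pt_to_soc populates SOC and flags unmapped PTs", {
  ptsoc <- data.frame(pt = c("Hepatitis", "Jaundice"),
                      soc = "hepatobiliary disorder")
  recs <- toy_records(data.frame(drug = "d1",
                                 event = c("Hepatitis", "Jaundice", "Rash")))
  out <- suppressMessages(map_pt_to_soc(recs, ptsoc))
  # many-to-one: both hepatic PTs carry the same SOC
  expect_equal(out$event_soc[1:2], rep("hepatobiliary disorder", 2))
  expect_true(out$soc_unmapped[3])
  # unmapped PT rows are excluded from the SOC rollup but kept at PT level
  m <- build_drug_event_matrix(out, "SOC")
  expect_equal(m$grand_total, 2L)
  expect_equal(build_drug_event_matrix(out, "PT")$grand_total, 3L)
  expect_error(map_pt_to_soc(recs, data.frame(pt = c("A", "A"),
                                              soc = c("s1", "s2"))),
               "exactly one")
})

test_that("drug-event matrix counts, marginals and round trip are exact", {
  m <- toy_matrix()
  expect_equal(matrix_count(m, "d1", "e1"), 2L)
  expect_equal(matrix_count(m, "d1", "e2"), 1L)
  expect_equal(matrix_count(m, "d2", "e1"), 1L)
  expect_equal(m$grand_total, 4L)
  expect_equal(m$drug_marginals, c(d1 = 3L, d2 = 1L))
  expect_equal(m$event_marginals, c(e1 = 3L, e2 = 1L))

  single <- build_drug_event_matrix(
    toy_records(data.frame(drug = "d9", event = "e9")), "PT")
  expect_equal(unname(single$drug_marginals), 1L)
  expect_equal(single$grand_total, 1L)

  # marginal consistency on simulated data
  g <- generate_reports(report_sim_config(n_reports = 2000, seed = 5))
  mm <- build_drug_event_matrix(g$records, "PT")
  expect_equal(sum(mm$drug_marginals), mm$grand_total)
  expect_equal(sum(mm$event_marginals), mm$grand_total)
  expect_equal(mm$grand_total, 2000L)
  for (d in names(mm$drug_marginals)[1:3])
    expect_equal(sum(mm$counts$count[mm$counts$drug == d]),
                 mm$drug_marginals[[d]])

  # write/read round trip reproduces counts exactly
  f <- tempfile(fileext = ".csv")
  write_matrix(mm, f)
  mm2 <- read_matrix(f, "PT")
  expect_equal(mm2$counts, mm$counts)
  expect_equal(mm2$grand_total, mm$grand_total)
})
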