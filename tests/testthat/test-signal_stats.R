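test_that("contingency_table cells follow the marginal arithmetic", {
  m <- toy_matrix()
  t1 <- contingency_table(m, "d1", "e1")
  expect_equal(unclass(t1)[c("a", "b", "c", "d")],
               list(a = 2L, b = 1L, c = 1L, d = 0L))
  # drug with zero target-event count
  t2 <- contingency_table(m, "d2", "e2")
  expect_equal(t2$a, 0L)
  expect_equal(t2$a + t2$b + t2$c + t2$d, m$grand_total)
  expect_error(contingency_table(m, "nope", "e1"), "not present")

  # synthetic generator cross-check: cells consistent with bookkeeping
  g <- generate_reports(report_sim_config(
    n_reports = 5000, planted_pairs = data.frame(drug = 1, event = 1,
                                                 multiplier = 4), seed = 3))
  mm <- build_drug_event_matrix(g$records, "PT")
  tt <- contingency_table(mm, "drug001", "event001")
  expect_equal(tt$a, matrix_count(mm, "drug001", "event001"))
  expect_equal(tt$a + tt$b, mm$drug_marginals[["drug001"]])
  expect_equal(tt$a + tt$c, mm$event_marginals[["event001"]])
})

test_that("RRR matches its closed form and independence gives exactly 1", {
  expect_equal(rrr(ct(10, 90, 190, 1710)), 1.0)     # independence
  expect_equal(rrr(ct(13, 87, 87, 1813)), 2.6)      # 13*2000/(100*100)
  expect_equal(rrr(ct(0, 10, 5, 85)), 0)            # zero numerator
  expect_error(rrr(ct(0, 0, 5, 95)), "zero marginal")
  # invariance under scaling all cells by a positive integer
  for (k in c(2, 5, 11))
    expect_equal(rrr(ct(13 * k, 87 * k, 87 * k, 1813 * k)), 2.6)
})

test_that("fisher_pvalue agrees with hand-enumerated tables", {
  # single attainable enrichment table: C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(fisher_pvalue(ct(5, 0, 0, 5)), 1 / 252, tolerance = 1e-12)
  # 3 attainable tables at margins (2,2,N=4): P(X >= 1) = 5/6
  expect_equal(fisher_pvalue(ct(1, 1, 1, 1)), 5 / 6, tolerance = 1e-12)
  # independence table shows no enrichment
  expect_gte(fisher_pvalue(ct(10, 90, 190, 1710)), 0.5)
  expect_equal(fisher_pvalue(ct(10, 90, 190, 1710)),
               fisher_enum_greater(10, 90, 190, 1710), tolerance = 1e-12)
  # two-sided agrees with the standard exact test
  expect_equal(fisher_pvalue(ct(7, 3, 2, 8), "two_sided"),
               stats::fisher.test(matrix(c(7, 3, 2, 8), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
})

test_that("greater-sided p decreases monotonically in a at fixed margins", {
  m <- 30; k <- 20; N <- 100
  as <- max(0, k - (N - m)):min(m, k)
  ps <- vapply(as, function(a)
    fisher_pvalue(ct(a, m - a, k - a, N - m - k + a)), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("detect_signals emits one record per drug with target reports", {
  recs <- toy_records(data.frame(
    drug = c("d1", "d1", "d1", "d2", "d3", "d3"),
    event = c("liver", "liver", "other", "other", "liver", "other")))
  m <- build_drug_event_matrix(recs, "PT")
  s <- detect_signals(m, "liver")
  expect_setequal(s$drug, c("d1", "d3"))  # d2 has no target reports
  expect_equal(s$reports[s$drug == "d1"], 2L)
  expect_true(all(s$pvalue >= 0 & s$pvalue <= 1))
  expect_error(detect_signals(m, "absent_event"), "not present")

  # planted strong signal is enriched; an independent drug is not
  g <- generate_reports(report_sim_config(
    n_reports = 20000, planted_pairs = data.frame(drug = 2, event = 4,
                                                  multiplier = 8),
    seed = 17))
  mm <- build_drug_event_matrix(g$records, "PT")
  ss <- detect_signals(mm, "event004")
  planted <- ss[ss$drug == "drug002", ]
  expect_gt(planted$rrr, 1)
  expect_lt(planted$pvalue, 0.05)
  other <- ss[ss$drug != "drug002", ]
  expect_lt(abs(mean(other$rrr) - 1), 0.15)  # null drugs hover around 1
})
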