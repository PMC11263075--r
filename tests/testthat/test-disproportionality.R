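test_that("build_table counts cases and non-cases under the PS-only rule", {
  # 6 hand-written reports: 2 PS-drugA+event, 1 C-drugA+event (must not count
  # as exposed), 1 PS-drugA without the event, 2 PS-other+event
  reports <- mk_reports(list(
    list(id = "r1", ps = "drugA", pts = "priapism"),
    list(id = "r2", ps = "drugA", pts = c("priapism", "nausea")),
    list(id = "r3", ps = "drugB", others = c(C = "drugA"), pts = "priapism"),
    list(id = "r4", ps = "drugA", pts = "nausea"),
    list(id = "r5", ps = "drugB", pts = "priapism"),
    list(id = "r6", ps = "drugC", pts = "priapism")
  ))
  tab <- build_table(reports, "drugA", "priapism")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]), c(a = 2L, b = 1L, c = 3L, d = 0L))

  # drug never mentioned -> no exposed reports
  tab0 <- build_table(reports, "drugZ", "priapism")
  expect_equal(tab0$a + tab0$b, 0L)

  # saturating event set -> every report is an event report
  tab_all <- build_table(reports, "drugA", c("priapism", "nausea"))
  expect_equal(tab_all$b, 0L)
  expect_equal(tab_all$d, 0L)

  expect_warning(
    z <- build_table(reports[0, ], "drugA", "priapism"),
    "empty report list"
  )
  expect_equal(z$n_total, 0L)
})

test_that("duplicate report_id rows collapse with last-wins PS resolution", {
  reports <- mk_reports(list(
    list(id = "r1", ps = "drugA", pts = "priapism"),
    list(id = "r1", ps = "drugB", pts = "priapism"),
    list(id = "r2", ps = "drugB", pts = "nausea")
  ))
  expect_message(tab <- build_table(reports, "drugB", "priapism"), "conflicting PS")
  expect_equal(tab$n_total, 2L)
  expect_equal(tab$a, 1L) # r1 resolves to drugB
})

test_that("ror_estimate follows the Woolf formula and flags zero cells", {
  tab <- structure(
    list(a = 10L, b = 90L, c = 100L, d = 9900L, n_total = 10100L),
    class = "contingency_table"
  )
  est <- ror_estimate(tab)
  expect_equal(est[["ror"]], 11.0)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(est[["ror_lo"]], exp(log(11) - 1.96 * se))
  expect_equal(est[["ror_hi"]], exp(log(11) + 1.96 * se))

  # balanced table: ROR 1 with a log-symmetric interval
  bal <- structure(
    list(a = 50L, b = 50L, c = 50L, d = 50L, n_total = 200L),
    class = "contingency_table"
  )
  est_b <- ror_estimate(bal)
  expect_equal(est_b[["ror"]], 1.0)
  expect_equal(log(est_b[["ror_hi"]]), -log(est_b[["ror_lo"]]))

  # doubling all cells keeps the estimate, narrows the interval
  dbl <- structure(
    list(a = 20L, b = 180L, c = 200L, d = 19800L, n_total = 20200L),
    class = "contingency_table"
  )
  est_d <- ror_estimate(dbl)
  expect_equal(est_d[["ror"]], est[["ror"]])
  expect_lt(est_d[["ror_hi"]] - est_d[["ror_lo"]], est[["ror_hi"]] - est[["ror_lo"]])

  # zero cell: undefined, never silently corrected
  zero <- structure(
    list(a = 0L, b = 10L, c = 5L, d = 100L, n_total = 115L),
    class = "contingency_table"
  )
  expect_true(all(is.na(ror_estimate(zero))))
})

test_that("ic_estimate implements the observed/expected shrinkage form", {
  # a exactly equal to its expectation: IC = 0
  tab <- structure(
    list(a = 10L, b = 90L, c = 90L, d = 810L, n_total = 1000L),
    class = "contingency_table"
  )
  e <- (10 + 90) * (10 + 90) / 1000
  expect_equal(e, 10)
  est <- ic_estimate(tab)
  expect_equal(est[["ic"]], 0)
  expect_lt(est[["ic_lo"]], est[["ic"]])

  # zero observed: shrinkage keeps the estimate finite and negative
  z <- structure(
    list(a = 0L, b = 100L, c = 100L, d = 800L, n_total = 1000L),
    class = "contingency_table"
  )
  est_z <- ic_estimate(z)
  expect_equal(est_z[["ic"]], log2(0.5 / (10 + 0.5)))
  expect_lt(est_z[["ic"]], 0)
  expect_lt(est_z[["ic_lo"]], est_z[["ic"]])

  # large observed vs small expectation, against the independent coding
  big <- structure(
    list(a = 100L, b = 0L, c = 0L, d = 9900L, n_total = 10000L),
    class = "contingency_table"
  )
  expect_equal(ic_estimate(big)[["ic"]], brute_ic(100, 0, 0, 9900)[["ic"]],
    tolerance = 1e-12
  )
})

test_that("oracle equivalence on random small report sets", {
  set.seed(424)
  for (i in 1:50) {
    reports <- random_reports(sample(10:40, 1))
    drug <- sample(c("dA", "dB", "dC"), 1)
    ev <- sample(c("pt1", "pt2", "pt3"), sample(1:2, 1))
    tab <- build_table(reports, drug, ev)
    oracle_counts <- brute_table(reports, drug, ev)
    expect_identical(
      unlist(tab[c("a", "b", "c", "d")]),
      oracle_counts
    )
    est <- ror_estimate(tab)
    oracle_est <- brute_ror(
      oracle_counts[["a"]], oracle_counts[["b"]],
      oracle_counts[["c"]], oracle_counts[["d"]]
    )
    if (is.na(oracle_est[["ror"]])) {
      expect_true(all(is.na(est)))
    } else {
      expect_identical(est[["ror"]], oracle_est[["ror"]])
      expect_equal(est[["ror_lo"]], oracle_est[["ror_lo"]], tolerance = 1e-12)
      expect_equal(est[["ror_hi"]], oracle_est[["ror_hi"]], tolerance = 1e-12)
    }
  }
})

test_that("ror and ic increase strictly in the case count", {
  mk <- function(a) {
    structure(
      list(a = a, b = 200L - a, c = 50L, d = 5000L, n_total = 5250L),
      class = "contingency_table"
    )
  }
  rors <- sapply(5:15, function(a) ror_estimate(mk(a))[["ror"]])
  ics <- sapply(5:15, function(a) ic_estimate(mk(a))[["ic"]])
  expect_true(all(diff(rors) > 0))
  expect_true(all(diff(ics) > 0))
})

test_that("the case-count inclusion filter reads 'greater than 3' strictly", {
  mk <- function(a) {
    structure(list(a = a, b = 10L, c = 10L, d = 100L, n_total = 120L + a),
      class = "contingency_table"
    )
  }
  expect_false(include_pt(mk(0L)))
  expect_false(include_pt(mk(3L)))
  expect_true(include_pt(mk(4L)))
})

test_that("signal_scan matches pairwise build_table and handles subgroups", {
  ts <- mini_termset()
  cfg <- null_config(n_reports = 5000, seed = 21, p_pt = 0.01)
  cfg$planted_effects <- data.frame(drug = "dA", pt = "priapism", rho = 12)
  reports <- generate_reports(cfg)
  drugs <- c("dA", "dB")
  sig <- signal_scan(reports, drugs, ts)

  # PT-level row equals a direct build_table + ror_estimate computation
  row <- sig[sig$drug == "dA" & sig$event == "priapism" & sig$level == "pt", ]
  tab <- build_table(reports, "dA", "priapism")
  expect_equal(row$a, tab$a)
  expect_equal(row$ror, unname(ror_estimate(tab)[["ror"]]))
  expect_equal(row$ic, unname(ic_estimate(tab)[["ic"]]))
  expect_true(row$significant_ror)
  expect_true(row$significant_ic)

  # subgroup semantics: the subgroup 2x2 counts a report once per subgroup
  sub_row <- sig[sig$drug == "dA" & sig$event == "erectile_dysfunction" &
    sig$level == "subgroup", ]
  sub_tab <- build_table(reports, "dA", subgroup_pts(ts, "erectile_dysfunction"))
  expect_equal(sub_row$a, sub_tab$a)
  expect_equal(sub_row$ror, unname(ror_estimate(sub_tab)[["ror"]]))

  # a singleton subgroup is identical to its member PT row
  ts1 <- termset(data.frame(
    pt = c("priapism", "anorgasmia"),
    hlgt = "sexual function and fertility disorders",
    subgroup = c("erectile_dysfunction", "none"),
    icd_flag = 0L
  ))
  sig1 <- signal_scan(reports, "dA", ts1)
  pt_row <- sig1[sig1$level == "pt" & sig1$event == "priapism", ]
  sg_row <- sig1[sig1$level == "subgroup" & sig1$event == "erectile_dysfunction", ]
  expect_equal(sg_row$ror, pt_row$ror)
  expect_equal(sg_row$a, pt_row$a)
})

test_that("median_ror takes the midpoint median over included PT estimates", {
  fake <- function(rors, included = TRUE, sig = TRUE) {
    data.frame(
      drug = rep("dA", length(rors)),
      event = paste0("pt", seq_along(rors), recycle0 = TRUE),
      level = rep("pt", length(rors)),
      ror = rors,
      included = rep(included, length.out = length(rors)),
      significant_ror = rep(sig, length.out = length(rors))
    )
  }
  expect_equal(median_ror(fake(c(2, 8)), "dA"), 5)
  expect_equal(median_ror(fake(c(1, 10, 100)), "dA"), 10)
  expect_equal(median_ror(fake(7), "dA"), 7)
  # excluded and undefined estimates never enter the median
  s <- rbind(fake(c(2, 8)), fake(1000)[1, ])
  s$included[3] <- FALSE
  expect_equal(median_ror(s, "dA"), 5)
  s2 <- fake(c(2, 8, NA))
  expect_message(m <- median_ror(s2, "dA"), "undefined")
  expect_equal(m, 5)
  expect_message(m0 <- median_ror(fake(numeric(0)), "dA"), "no included")
  expect_true(is.na(m0))
  # significant-only variant
  s3 <- fake(c(2, 8, 50), sig = c(FALSE, TRUE, TRUE))
  expect_equal(median_ror(s3, "dA", over = "significant"), 29)
})
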