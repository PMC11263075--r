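test_that("fit_univariate reproduces hand-computed OLS and its edge cases", {
  # 3-point hand example: x = {0,1,2}, y = {1,1,4}
  f <- fit_univariate(c(0, 1, 2), c(1, 1, 4))
  expect_equal(f$beta, 1.5)
  expect_equal(f$intercept, 0.5)
  expect_equal(f$r2, 0.75)

  # noiseless line
  x <- 1:5
  f2 <- fit_univariate(x, 2 * x + 1)
  expect_equal(f2$beta, 2)
  expect_equal(f2$intercept, 1)
  expect_equal(f2$r2, 1)
  expect_gt(f2$p_value, 0)

  # flat response
  f3 <- fit_univariate(1:5, rep(3, 5))
  expect_equal(f3$beta, 0)
  expect_equal(f3$r2, 0)
  expect_equal(f3$p_value, 1)

  expect_error(fit_univariate(rep(2, 4), 1:4), "degenerate predictor")
  expect_error(fit_univariate(1:2, 1:2), "at least 3")
})

test_that("fit_univariate agrees with the closed-form OLS oracle", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    x <- rnorm(n)
    y <- 1.3 * x + rnorm(n)
    f <- fit_univariate(x, y)
    o <- brute_ols(x, y)
    expect_equal(f$beta, o[["beta"]], tolerance = 1e-10)
    expect_equal(f$intercept, o[["intercept"]], tolerance = 1e-10)
    expect_equal(f$p_value, o[["p"]], tolerance = 1e-10)
    expect_equal(f$r2, o[["r2"]], tolerance = 1e-10)
    # OLS identities
    res <- residuals(f$lm)
    expect_lt(abs(sum(res * (x - mean(x)))), 1e-9)
    expect_equal(f$r2, 1 - sum(res^2) / sum((y - mean(y))^2), tolerance = 1e-10)
    expect_equal(f$r2, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("OLS is affine-equivariant in the predictor", {
  set.seed(7)
  x <- rnorm(8)
  y <- 2 * x + rnorm(8, sd = 0.5)
  f <- fit_univariate(x, y)
  fk <- fit_univariate(10 * x + 3, y)
  expect_equal(fk$beta, f$beta / 10, tolerance = 1e-12)
  expect_equal(fk$p_value, f$p_value, tolerance = 1e-12)
  expect_equal(fk$r2, f$r2, tolerance = 1e-12)
})

test_that("eligible_receptors enforces the three-drug minimum", {
  occ <- data.frame(
    drug = c("a", "b", "a", "b", "c"),
    receptor = c("D2", "D2", "D3", "D3", "D3"),
    occupancy_pct = c(10, 20, 30, 40, NA)
  )
  expect_equal(eligible_receptors(occ), character(0))
  occ$occupancy_pct[5] <- 50
  expect_equal(eligible_receptors(occ), "D3")
  expect_equal(eligible_receptors(occ[0, ]), character(0))
})

test_that("the regression suite recovers a planted occupancy-ROR slope", {
  set.seed(31)
  drugs <- paste0("drug", 1:11)
  occ_vals <- seq(5, 95, length.out = 11)
  hits <- 0L
  for (s in 1:20) {
    y <- 1 + 4.5 * occ_vals / 10 + rnorm(11, sd = 1)
    x <- occ_vals / 10
    f <- fit_univariate(x, y)
    se <- sqrt(sum(residuals(f$lm)^2) / 9 / sum((x - mean(x))^2))
    if (abs(f$beta - 4.5) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, 17L) # ~95% nominal coverage of +-2 SE
})

test_that("pvpd assembles per-receptor fits with mode semantics", {
  ts <- mini_termset()
  cfg <- null_config(n_reports = 15000, seed = 13, p_pt = 0.01)
  sd <- sd_event_pts(ts)
  cfg$planted_effects <- data.frame(
    drug = rep(c("dA", "dB"), each = 2),
    pt = c("priapism", "anorgasmia", "priapism", "erectile dysfunction"),
    rho = c(10, 6, 3, 8)
  )
  reports <- generate_reports(cfg)
  drugs <- c("dA", "dB", "dC", "dD")
  sig <- signal_scan(reports, drugs, ts)

  occ <- data.frame(
    drug = rep(drugs, times = 2),
    receptor = rep(c("D2", "5-HT1A"), each = 4),
    occupancy_pct = c(80, 60, 30, 10, 20, 50, 70, 40),
    signed_occupancy = c(-80, 60, -30, 10, 20, -50, 70, NA),
    pki = c(9, 8.5, 7, 6, 6.5, 7.5, 8, 7.2)
  )
  fit <- pvpd(sig, occ, ts, exclude_drugs = character())
  expect_s3_class(fit, "pvpd_fit")
  expect_true(all(fit$table$n_points >= 3))
  expect_setequal(unique(fit$table$mode), pvpd:::PVPD_MODES)

  # activity_signed drops the drug with unknown activity on 5-HT1A
  as_row <- fit$table[fit$table$mode == "activity_signed" &
    fit$table$receptor == "5-HT1A", ]
  expect_equal(as_row$n_points, 3)

  # the main fit equals a direct fit_univariate on the same drugs
  y <- sapply(drugs, function(d) median_ror(sig, d))
  keep <- !is.na(y)
  d2 <- occ[occ$receptor == "D2", ]
  x <- setNames(d2$occupancy_pct, d2$drug)[names(y)[keep]]
  direct <- fit_univariate(x, y[keep])
  main_row <- fit$table[fit$table$mode == "main" & fit$table$receptor == "D2", ]
  expect_equal(main_row$beta, direct$beta)
  expect_equal(main_row$r2, direct$r2)

  # pKi mode: same receptor, different predictor, still a valid fit
  pki_row <- fit$table[fit$table$mode == "pki" & fit$table$receptor == "D2", ]
  expect_true(is.finite(pki_row$beta))

  # excluding a drug removes it from every fit's input
  fit_ex <- pvpd(sig, occ, ts, mode = "main", exclude_drugs = "dA")
  expect_false("dA" %in% unlist(lapply(fit_ex$fits, `[[`, "drugs")))

  # a mode reducing a receptor below 3 points drops it with a notice
  occ2 <- occ
  occ2$signed_occupancy[occ2$receptor == "D2"][1:2] <- NA
  expect_message(
    fit2 <- pvpd(sig, occ2, ts, mode = "activity_signed", exclude_drugs = character()),
    "dropped in mode"
  )
  expect_false("D2" %in% fit2$table$receptor)
})

test_that("pvpd_fit methods expose coefficients, predictions and residuals", {
  set.seed(5)
  sig <- do.call(rbind, lapply(paste0("d", 1:5), function(d) {
    data.frame(
      drug = d, event = paste0("pt", 1:3), level = "pt",
      ror = runif(3, 1, 8), included = TRUE, significant_ror = TRUE
    )
  }))
  occ <- data.frame(
    drug = paste0("d", 1:5), receptor = "D2",
    occupancy_pct = c(10, 30, 50, 70, 90),
    signed_occupancy = c(10, 30, 50, 70, 90),
    pki = 6:10
  )
  fit <- pvpd(sig, occ, mode = "main", exclude_drugs = character())
  cf <- coef(fit)
  expect_equal(rownames(cf), "main.D2")
  expect_equal(unname(cf[1, "beta"]), fit$table$beta[1])
  pr <- predict(fit, "D2", newdata = c(0, 100))
  expect_length(pr, 2)
  expect_equal(unname(diff(pr)), fit$table$beta[1] * 100)
  expect_length(residuals(fit)[["main.D2"]], 5)
  expect_output(print(fit), "main")
  expect_output(print(summary(fit)), "regression summary")
  sm <- summary(fit, p_adjust = TRUE)
  expect_true("p_bh" %in% names(sm$table))
  expect_gte(sm$table$p_bh[1], sm$table$p_value[1])
})
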