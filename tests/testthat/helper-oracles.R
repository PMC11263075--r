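# Independent oracles and fixture builders. The oracles recount and
# recompute everything from first principles, without calling the package's
# counting or estimation code paths.

# Build a flat report table from per-report descriptions.
# Each element of `specs` is list(id, ps = drug or NULL, others = named
# character of extra drug entries role->drug, pts = character, quarter).
mk_reports <- function(specs) {
  rows <- list()
  for (s in specs) {
    q <- if (is.null(s$quarter)) "2010Q1" else s$quarter
    drugs <- character()
    roles <- character()
    if (!is.null(s$ps)) {
      drugs <- c(drugs, s$ps)
      roles <- c(roles, "PS")
    }
    if (!is.null(s$others)) {
      drugs <- c(drugs, unname(s$others))
      roles <- c(roles, names(s$others))
    }
    for (k in seq_along(drugs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        report_id = s$id, drug = drugs[k], role = roles[k], pt = s$pts,
        age = NA_real_, sex = NA_character_, country = NA_character_,
        quarter = q, indication = NA_character_, outcome = NA_character_,
        daily_dose_mg = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("faers_reports", "data.frame"))
}

# Brute-force 2x2 recount: loops over unique report ids one at a time.
brute_table <- function(reports, drug, event_pts) {
  event_pts <- tolower(trimws(event_pts))
  ids <- unique(reports$report_id)
  a <- b <- cc <- d <- 0L
  for (id in ids) {
    sub <- reports[reports$report_id == id, ]
    ps_rows <- sub[sub$role == "PS", "drug"]
    ps_drug <- if (length(ps_rows)) ps_rows[length(ps_rows)] else NA_character_
    exposed <- !is.na(ps_drug) && ps_drug == drug
    has_event <- any(tolower(trimws(sub$pt)) %in% event_pts)
    if (exposed && has_event) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (has_event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Independent odds ratio + Woolf interval from the four counts.
brute_ror <- function(a, b, cc, d) {
  if (min(a, b, cc, d) < 1) return(c(ror = NA, ror_lo = NA, ror_hi = NA))
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  c(ror = or, ror_lo = exp(log(or) - 1.96 * se), ror_hi = exp(log(or) + 1.96 * se))
}

# Independent information-component shrinkage formula.
brute_ic <- function(a, b, cc, d) {
  n <- a + b + cc + d
  e <- (a + b) * (a + cc) / n
  ic <- log((a + 0.5) / (e + 0.5)) / log(2)
  c(ic = ic, ic_lo = ic - 3.3 / sqrt(a + 0.5) - 2.0 / (a + 0.5)^1.5)
}

# Closed-form OLS on (x, y): slope, intercept, two-sided p, R^2.
brute_ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  beta <- sum((x - mx) * (y - my)) / sxx
  alpha <- my - beta * mx
  res <- y - alpha - beta * x
  sse <- sum(res^2)
  sst <- sum((y - my)^2)
  s2 <- sse / (n - 2)
  tstat <- beta / sqrt(s2 / sxx)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  c(beta = beta, intercept = alpha, p = p, r2 = 1 - sse / sst)
}

# Random small report sets for the oracle-equivalence property.
random_reports <- function(n_reports, drugs = c("dA", "dB", "dC"),
                           pts = c("pt1", "pt2", "pt3")) {
  specs <- lapply(seq_len(n_reports), function(i) {
    n_pt <- sample(1:3, 1)
    others <- NULL
    if (stats::runif(1) < 0.4) {
      others <- stats::setNames(sample(drugs, 1), sample(c("C", "SS", "I"), 1))
    }
    list(
      id = sprintf("X%04d", i),
      ps = if (stats::runif(1) < 0.9) sample(drugs, 1) else NULL,
      others = others,
      pts = sample(pts, n_pt)
    )
  })
  mk_reports(specs)
}

# A compact four-subgroup term set for generator-driven tests.
mini_termset <- function() {
  termset(data.frame(
    pt = c(
      "compulsive sexual behavior", "libido increased",
      "libido decreased", "anorgasmia",
      "erectile dysfunction", "priapism",
      "retrograde ejaculation", "ejaculation failure",
      "sexual dysfunction"
    ),
    hlgt = c(
      "sexual dysfunctions, disturbances and gender identity disorders",
      rep("sexual function and fertility disorders", 8)
    ),
    subgroup = c(
      "hypersexuality", "hypersexuality",
      "hyposexuality", "hyposexuality",
      "erectile_dysfunction", "erectile_dysfunction",
      "ejaculatory_dysfunction", "ejaculatory_dysfunction",
      "none"
    ),
    icd_flag = c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  ))
}

# Small null (rho = 1) generator config over the mini term set.
null_config <- function(n_reports = 20000, seed = 1L, p_pt = 0.005) {
  ts <- mini_termset()
  sd <- sd_event_pts(ts)
  faers_config(
    n_reports = n_reports,
    drugs = c(background = 0.6, dA = 0.1, dB = 0.1, dC = 0.1, dD = 0.1),
    pts = stats::setNames(rep(p_pt, length(sd)), sd),
    icd_pts = character(),
    concomitant_rate = 0.2,
    seed = seed
  )
}
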