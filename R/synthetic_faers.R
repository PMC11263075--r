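#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes a FAERS-like stream of individual case safety reports: one
#' primary-suspect (PS) drug per report drawn from drug marginals, reaction
#' PTs included conditionally independently given the PS drug, planted
#' drug-PT reporting-rate multipliers (rho; rho = 1 means independence),
#' an optional post-warning reporting surge for impulse-control-disorder
#' (ICD) PTs, and Table-1-style demographics. Conditional independence of PT
#' inclusion given the PS drug is what makes the population reporting odds
#' ratio of every pair available in closed form via [expected_ror()].
#'
#' @param n_reports number of reports to generate.
#' @param drugs named numeric vector: drug names with background marginal
#'   probabilities of being the PS drug; must sum to 1.
#' @param pts named numeric vector: PT names with background per-report
#'   inclusion probabilities (each in \[0,1\]; they need not sum to 1).
#' @param planted_effects data frame with columns `drug`, `pt`, `rho`
#'   giving reporting-rate multipliers (rho >= 0); pairs not listed default
#'   to rho = 1 (no association).
#' @param quarter_start,quarter_end receipt-quarter range, default
#'   2004Q1-2023Q3.
#' @param warning_surge `NULL`, or a list with `cut` (quarter string,
#'   default `"2016Q2"`, the May-2016 FDA warning quarter), `multiplier`
#'   (applied to ICD PT inclusion probabilities in quarters strictly after
#'   the cut) and optional `drugs` (character vector restricting the surge
#'   to some PS drugs; `NULL` = all drugs, emulating spill-over notoriety).
#' @param icd_pts character vector of ICD-related PTs the surge applies to;
#'   defaults to the ICD PTs of the shipped default term set.
#' @param demographics list of named probability vectors `age_band`
#'   (names "18-40", "41-65", ">65", "missing"), `sex` (F/M/missing),
#'   `country`, `indication`, `outcome`
#'   (death_lifethreat/hospitalization/other); each must sum to 1.
#' @param dose_missingness fraction of reports without dose information,
#'   default 0.758 (spontaneous-report dosage fields are mostly empty).
#' @param concomitant_rate fraction of reports carrying one additional
#'   concomitant (role C) drug entry; decoys that the PS-only filter must
#'   ignore.
#' @param seed integer seed; identical seed gives a byte-identical dataset.
#' @return an object of class `faers_config`.
#' @export
faers_config <- function(n_reports,
                         drugs,
                         pts,
                         planted_effects = NULL,
                         quarter_start = "2004Q1",
                         quarter_end = "2023Q3",
                         warning_surge = NULL,
                         icd_pts = NULL,
                         demographics = NULL,
                         dose_missingness = 0.758,
                         concomitant_rate = 0.3,
                         seed = 1L) {
  stopifnot(length(n_reports) == 1L, n_reports >= 1)
  if (is.null(names(drugs)) || any(names(drugs) == "")) {
    stop("drugs must be a named probability vector")
  }
  if (abs(sum(drugs) - 1) > 1e-9) stop("drug marginal probabilities must sum to 1")
  if (any(drugs < 0)) stop("drug probabilities must be nonnegative")
  if (is.null(names(pts)) || any(names(pts) == "")) {
    stop("pts must be a named probability vector")
  }
  names(pts) <- normalize_pt(names(pts))
  if (any(pts < 0 | pts > 1)) stop("PT probabilities must lie in [0,1]")
  quarters <- quarter_seq(quarter_start, quarter_end) # validates the range

  if (!is.null(planted_effects)) {
    stopifnot(all(c("drug", "pt", "rho") %in% names(planted_effects)))
    planted_effects$pt <- normalize_pt(planted_effects$pt)
    if (any(planted_effects$rho < 0)) stop("rho must be >= 0")
    unknown <- setdiff(planted_effects$drug, names(drugs))
    if (length(unknown)) stop("planted effect for unknown drug: ", paste(unknown, collapse = ", "))
    unknown <- setdiff(planted_effects$pt, names(pts))
    if (length(unknown)) stop("planted effect for unknown PT: ", paste(unknown, collapse = ", "))
  }

  if (is.null(icd_pts)) {
    ts_path <- system.file("extdata", "termset.csv", package = "pvpd")
    icd_pts <- if (nzchar(ts_path)) icd_pts(read_termset(ts_path)) else character()
  }
  icd_pts <- normalize_pt(icd_pts)

  if (!is.null(warning_surge)) {
    if (is.null(warning_surge$cut)) warning_surge$cut <- "2016Q2"
    quarter_index(warning_surge$cut) # validate
    stopifnot(is.numeric(warning_surge$multiplier), warning_surge$multiplier >= 0)
  }

  if (is.null(demographics)) demographics <- default_demographics()
  for (nm in names(demographics)) {
    p <- demographics[[nm]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("demographic distribution '", nm, "' must be a probability vector summing to 1")
    }
  }
  stopifnot(dose_missingness >= 0, dose_missingness <= 1)
  stopifnot(concomitant_rate >= 0, concomitant_rate <= 1)

  structure(
    list(
      n_reports = as.integer(n_reports), drugs = drugs, pts = pts,
      planted_effects = planted_effects,
      quarter_start = quarter_start, quarter_end = quarter_end,
      quarters = quarters,
      warning_surge = warning_surge, icd_pts = icd_pts,
      demographics = demographics,
      dose_missingness = dose_missingness,
      concomitant_rate = concomitant_rate,
      seed = as.integer(seed)
    ),
    class = "faers_config"
  )
}

# Table-1-style marginal distributions for report demographics.
default_demographics <- function() {
  list(
    age_band = c("18-40" = 0.45, "41-65" = 0.17, ">65" = 0.015, "missing" = 0.365),
    sex = c(F = 0.25, M = 0.62, missing = 0.13),
    country = c(US = 0.55, other = 0.45),
    indication = c(
      "psychotic disorder" = 0.35, "bipolar disorder" = 0.12,
      "other" = 0.53
    ),
    outcome = c(death_lifethreat = 0.037, hospitalization = 0.215, other = 0.748)
  )
}

# rho lookup matrix (drugs x pts), default 1
rho_matrix <- function(config) {
  m <- matrix(1, length(config$drugs), length(config$pts),
    dimnames = list(names(config$drugs), names(config$pts))
  )
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    m[cbind(pe$drug, pe$pt)] <- pe$rho
  }
  m
}

# does the warning surge apply to (drug, pt) in a post-cut quarter?
surge_applies <- function(config, drug, pt) {
  ws <- config$warning_surge
  if (is.null(ws)) return(FALSE)
  if (!(pt %in% config$icd_pts)) return(FALSE)
  is.null(ws$drugs) || drug %in% ws$drugs
}

#' Generate a synthetic spontaneous-report dataset
#'
#' Draws `n_reports` reports: a PS drug from the drug marginals, a receipt
#' quarter (uniform over the configured range), reaction PTs included
#' independently with probability `p_pt * rho(drug, pt)` (capped at 1 with a
#' warning naming the pair), the ICD-PT surge multiplier applied in quarters
#' strictly after the warning cut, and demographics from the configured
#' categorical distributions. A report whose PT draws all come up empty
#' receives the background filler PT `"product ineffective"` (never part of
#' a term set) so every report has a non-empty reaction list without
#' perturbing any analyzed PT's inclusion probability. A fraction of reports
#' carries a decoy concomitant (role C) drug entry.
#'
#' @param config a [faers_config()].
#' @return a `faers_reports` object: a data frame in flat long form, one row
#'   per report x drug-entry x PT, with columns
#'   `report_id, drug, role, pt, age, sex, country, quarter, indication,
#'   outcome, daily_dose_mg`, and the config stored in
#'   `attr(, "config")`.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "faers_config"))
  with_seed(config$seed, {
    n <- config$n_reports
    drug_names <- names(config$drugs)
    pt_names <- names(config$pts)
    ps <- sample(drug_names, n, replace = TRUE, prob = config$drugs)
    quarter <- sample(config$quarters, n, replace = TRUE)

    post <- if (is.null(config$warning_surge)) {
      rep(FALSE, n)
    } else {
      quarter_index(quarter) > quarter_index(config$warning_surge$cut)
    }

    rho <- rho_matrix(config)
    ps_row <- match(ps, drug_names)

    incl_idx <- vector("list", length(pt_names))
    for (j in seq_along(pt_names)) {
      pt <- pt_names[j]
      p <- config$pts[[j]] * rho[ps_row, j]
      if (!is.null(config$warning_surge) && pt %in% config$icd_pts) {
        surged_drug <- if (is.null(config$warning_surge$drugs)) {
          rep(TRUE, n)
        } else {
          ps %in% config$warning_surge$drugs
        }
        mult <- ifelse(post & surged_drug, config$warning_surge$multiplier, 1)
        p <- p * mult
      }
      if (any(p > 1)) {
        over <- unique(ps[p > 1])
        warning(
          "inclusion probability capped at 1 for pair(s): ",
          paste(paste0("(", over, ", ", pt, ")"), collapse = ", ")
        )
        p <- pmin(p, 1)
      }
      incl_idx[[j]] <- which(stats::runif(n) < p)
    }

    long_i <- unlist(incl_idx, use.names = FALSE)
    long_pt <- rep(pt_names, lengths(incl_idx))
    # filler for reports with no sampled PT: keeps the reaction list non-empty
    empty <- setdiff(seq_len(n), long_i)
    if (length(empty)) {
      long_i <- c(long_i, empty)
      long_pt <- c(long_pt, rep("product ineffective", length(empty)))
    }
    ord <- order(long_i, long_pt)
    long_i <- long_i[ord]
    long_pt <- long_pt[ord]

    # report-level demographics
    dg <- config$demographics
    band <- sample(names(dg$age_band), n, replace = TRUE, prob = dg$age_band)
    age <- rep(NA_real_, n)
    age[band == "18-40"] <- round(stats::runif(sum(band == "18-40"), 18, 40), 1)
    age[band == "41-65"] <- round(stats::runif(sum(band == "41-65"), 41, 65), 1)
    age[band == ">65"] <- round(stats::runif(sum(band == ">65"), 66, 90), 1)
    sex <- sample(names(dg$sex), n, replace = TRUE, prob = dg$sex)
    sex[sex == "missing"] <- NA_character_
    country <- sample(names(dg$country), n, replace = TRUE, prob = dg$country)
    indication <- sample(names(dg$indication), n, replace = TRUE, prob = dg$indication)
    outcome <- sample(names(dg$outcome), n, replace = TRUE, prob = dg$outcome)
    dose <- round(stats::rlnorm(n, meanlog = log(10), sdlog = 0.6), 1)
    dose[stats::runif(n) < config$dose_missingness] <- NA_real_

    rid <- sprintf("R%07d", seq_len(n))
    ps_rows <- data.frame(
      report_id = rid[long_i], drug = ps[long_i], role = "PS", pt = long_pt,
      age = age[long_i], sex = sex[long_i], country = country[long_i],
      quarter = quarter[long_i], indication = indication[long_i],
      outcome = outcome[long_i], daily_dose_mg = dose[long_i],
      stringsAsFactors = FALSE
    )

    has_c <- stats::runif(n) < config$concomitant_rate
    c_drug <- sample(drug_names, n, replace = TRUE, prob = config$drugs)
    keep <- has_c[long_i]
    out <- if (any(keep)) {
      c_rows <- ps_rows[keep, ]
      c_rows$drug <- c_drug[long_i[keep]]
      c_rows$role <- rep("C", nrow(c_rows))
      rbind(ps_rows, c_rows)
    } else {
      ps_rows
    }
    out <- out[order(out$report_id, out$role != "PS", out$drug, out$pt), ]
    rownames(out) <- NULL
    structure(out, class = c("faers_reports", "data.frame"), config = config)
  })
}

#' Write a synthetic dataset to CSV with a config sidecar
#'
#' @param reports a `faers_reports` data frame.
#' @param path output CSV path; a JSON sidecar `<path>.config.json` echoing
#'   the generating configuration (including the seed) is written alongside
#'   for provenance.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  utils::write.csv(as.data.frame(reports), path, row.names = FALSE, quote = TRUE)
  cfg <- attr(reports, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(
      unclass(cfg)[setdiff(names(cfg), "quarters")],
      paste0(path, ".config.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

#' Read a flat report table from CSV
#'
#' Accepts the schema emitted by [write_reports()] (also the shape of
#' OpenVigil-style tabulated exports): one row per report x drug-entry x PT.
#'
#' @param path CSV path.
#' @return a `faers_reports` data frame.
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("report_id", "drug", "role", "pt")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("report table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$pt <- normalize_pt(df$pt)
  structure(df, class = c("faers_reports", "data.frame"))
}

# per-drug inclusion probability of `pt`, averaged over the quarter mix
# (overriding rho with 1 when base = TRUE)
pair_inclusion_probs <- function(config, pt, base = FALSE) {
  drug_names <- names(config$drugs)
  p0 <- config$pts[[pt]]
  rho <- if (base) {
    stats::setNames(rep(1, length(drug_names)), drug_names)
  } else {
    rho_matrix(config)[, pt]
  }
  ws <- config$warning_surge
  n_q <- length(config$quarters)
  w_post <- if (is.null(ws)) 0 else {
    sum(quarter_index(config$quarters) > quarter_index(ws$cut)) / n_q
  }
  q <- numeric(length(drug_names))
  names(q) <- drug_names
  for (d in drug_names) {
    r <- rho[[d]]
    if (surge_applies(config, d, pt)) {
      q[[d]] <- (1 - w_post) * min(1, p0 * r) + w_post * min(1, p0 * r * ws$multiplier)
    } else {
      q[[d]] <- min(1, p0 * r)
    }
  }
  q
}

#' Population reporting odds ratio implied by a generator configuration
#'
#' The ground-truth oracle for planted associations: computes, by exact
#' enumeration over the generator's mixture (for each possible PS drug the
#' quarter-averaged PT inclusion probability), the population odds of the PT
#' among reports with `drug` as PS divided by its odds among all other
#' reports. With rho = 1 everywhere this is exactly 1; with rho = 0 for a
#' pair it is 0.
#'
#' @param config a [faers_config()].
#' @param drug,pt the pair to evaluate; must exist in the config.
#' @return the population ROR (nonnegative; `Inf` if the event is certain
#'   under the drug and not otherwise).
#' @export
expected_ror <- function(config, drug, pt) {
  stopifnot(inherits(config, "faers_config"))
  pt <- normalize_pt(pt)
  if (!drug %in% names(config$drugs)) stop("unknown drug: ", drug)
  if (!pt %in% names(config$pts)) stop("unknown PT: ", pt)
  q <- pair_inclusion_probs(config, pt)
  probs <- config$drugs
  p_t <- q[[drug]]
  w_other <- probs[names(probs) != drug]
  if (sum(w_other) <= 0) stop("no comparator drugs in config")
  p_o <- sum(w_other * q[names(w_other)]) / sum(w_other)
  if (p_t == 0) return(0)
  if (p_t >= 1) return(Inf)
  if (p_o == 0) return(Inf)
  (p_t / (1 - p_t)) / (p_o / (1 - p_o))
}

#' Solve for the rate multiplier that plants a target population ROR
#'
#' Inverts [expected_ror()] for one pair, holding every other pair's rho
#' fixed: returns the rho such that the generator's population ROR for
#' (`drug`, `pt`) equals `target_ror`.
#'
#' @inheritParams expected_ror
#' @param target_ror desired population ROR (> 0).
#' @return the required rho (reporting-rate multiplier).
#' @export
calibrate_rho <- function(config, drug, pt, target_ror) {
  stopifnot(target_ror > 0)
  pt <- normalize_pt(pt)
  if (!drug %in% names(config$drugs)) stop("unknown drug: ", drug)
  if (!pt %in% names(config$pts)) stop("unknown PT: ", pt)
  q <- pair_inclusion_probs(config, pt)
  probs <- config$drugs
  w_other <- probs[names(probs) != drug]
  p_o <- sum(w_other * q[names(w_other)]) / sum(w_other)
  if (p_o <= 0 || p_o >= 1) stop("comparator event probability degenerate: ", p_o)
  odds_t <- target_ror * p_o / (1 - p_o)
  q_t <- odds_t / (1 + odds_t)
  base <- pair_inclusion_probs(config, pt, base = TRUE)[[drug]]
  if (q_t > 1 - 1e-12) stop("target ROR unreachable: implied probability ", q_t)
  q_t / base
}

#' @export
print.faers_config <- function(x, ...) {
  cat(
    "Synthetic report-stream config:", x$n_reports, "reports,",
    length(x$drugs), "drugs,", length(x$pts), "PTs,",
    x$quarter_start, "-", x$quarter_end, "\n"
  )
  n_eff <- if (is.null(x$planted_effects)) 0L else nrow(x$planted_effects)
  cat(
    "planted effects:", n_eff,
    "| warning surge:", if (is.null(x$warning_surge)) "none" else {
      paste0("x", x$warning_surge$multiplier, " after ", x$warning_surge$cut)
    },
    "| seed:", x$seed, "\n"
  )
  invisible(x)
}
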