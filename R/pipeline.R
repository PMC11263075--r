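#' Per-drug descriptive summary of the SD case series
#'
#' For each target drug, summarizes the reports where the drug is the
#' primary suspect and any SD PT is reported: case count, age bands (18-40,
#' 41-65, >65, unknown), mean/SD age, sex, country, indication and outcome
#' splits, five-year-period counts (2004-2008, 2009-2013, 2014-2018,
#' 2019-2023) and mean daily dose with the number of dosed reports.
#'
#' @param reports a `faers_reports` data frame.
#' @param drugs character vector of target drugs.
#' @param ts a `termset`.
#' @return long data frame `drug, statistic, value`.
#' @export
describe_cohort <- function(reports, drugs, ts) {
  stopifnot(inherits(ts, "termset"))
  sd_pts <- sd_event_pts(ts)
  ps <- report_ps_map(reports)
  ev_ids <- event_report_ids(reports, sd_pts)
  # report-level attributes from the first row of each report
  first <- reports[!duplicated(reports$report_id), ]
  first <- first[match(ps$report_id, first$report_id), ]

  periods <- list(
    "2004-2008" = 2004:2008, "2009-2013" = 2009:2013,
    "2014-2018" = 2014:2018, "2019-2023" = 2019:2023
  )
  out <- list()
  for (dg in drugs) {
    case <- !is.na(ps$ps_drug) & ps$ps_drug == dg & ps$report_id %in% ev_ids
    n <- sum(case)
    f <- first[case, , drop = FALSE]
    stat <- function(statistic, value) {
      data.frame(drug = dg, statistic = statistic, value = value)
    }
    age <- f$age
    yr <- if (n) quarter_year(f$quarter) else integer()
    rows <- list(
      stat("n_cases", n),
      stat("age_18_40", sum(!is.na(age) & age >= 18 & age <= 40)),
      stat("age_41_65", sum(!is.na(age) & age > 40 & age <= 65)),
      stat("age_over_65", sum(!is.na(age) & age > 65)),
      stat("age_unknown", sum(is.na(age))),
      stat("mean_age", if (any(!is.na(age))) mean(age, na.rm = TRUE) else NA_real_),
      stat("sd_age", if (sum(!is.na(age)) > 1) stats::sd(age, na.rm = TRUE) else NA_real_),
      stat("sex_f", sum(!is.na(f$sex) & f$sex == "F")),
      stat("sex_m", sum(!is.na(f$sex) & f$sex == "M")),
      stat("sex_unknown", sum(is.na(f$sex))),
      stat("country_us", sum(!is.na(f$country) & f$country == "US")),
      stat("country_other", sum(is.na(f$country) | f$country != "US")),
      stat("indication_psychotic", sum(f$indication == "psychotic disorder", na.rm = TRUE)),
      stat("indication_bipolar", sum(f$indication == "bipolar disorder", na.rm = TRUE)),
      stat(
        "indication_other",
        n - sum(f$indication %in% c("psychotic disorder", "bipolar disorder"), na.rm = TRUE)
      ),
      stat("outcome_death_lifethreat", sum(f$outcome == "death_lifethreat", na.rm = TRUE)),
      stat("outcome_hospitalization", sum(f$outcome == "hospitalization", na.rm = TRUE)),
      stat(
        "outcome_other",
        n - sum(f$outcome %in% c("death_lifethreat", "hospitalization"), na.rm = TRUE)
      )
    )
    for (p in names(periods)) {
      rows <- c(rows, list(
        stat(paste0("period_", gsub("-", "_", p)), sum(yr %in% periods[[p]]))
      ))
    }
    dosed <- !is.na(f$daily_dose_mg)
    rows <- c(rows, list(
      stat("mean_dose_mg", if (any(dosed)) mean(f$daily_dose_mg[dosed]) else NA_real_),
      stat("n_dose_available", sum(dosed))
    ))
    out[[dg]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Configuration for an end-to-end pipeline run
#'
#' @param input a `faers_config` (reports are generated) or a path to a
#'   flat report CSV.
#' @param termset a `termset` object or path; default the shipped term set.
#' @param pharmacology a `pharmacology` data frame or path; default the
#'   shipped synthetic demonstration table.
#' @param drugs target drugs; default the drugs of the pharmacology table.
#' @param exclude_drugs drugs excluded from regression inputs, default
#'   `"iloperidone"`.
#' @param median_over `"included"` or `"significant"`.
#' @param modes regression modes, default all four.
#' @param sensitivity a [sensitivity_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing every random draw of the run.
#' @return a `run_config` list.
#' @export
run_config <- function(input, termset = NULL, pharmacology = NULL,
                       drugs = NULL, exclude_drugs = "iloperidone",
                       median_over = "included", modes = PVPD_MODES,
                       sensitivity = sensitivity_spec(),
                       out_dir, seed = 1L) {
  ts <- if (is.null(termset)) {
    default_termset()
  } else if (inherits(termset, "termset")) termset else read_termset(termset)
  ph <- if (is.null(pharmacology)) {
    demo_pharmacology()
  } else if (inherits(pharmacology, "data.frame") && !is.character(pharmacology)) {
    pharmacology
  } else {
    read_pharmacology(pharmacology)
  }
  if (is.null(drugs)) drugs <- unique(ph$drug)
  if (!length(drugs)) stop("drug list is empty")
  if (is.character(input) && !file.exists(input)) {
    stop("input report file not found: ", input)
  }
  structure(
    list(
      input = input, termset = ts, pharmacology = ph, drugs = drugs,
      exclude_drugs = exclude_drugs, median_over = median_over,
      modes = modes, sensitivity = sensitivity,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

write_table <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = TRUE)
}

#' Run the full analysis pipeline
#'
#' Ingests (or generates) the report stream, then runs every stage in
#' order: cohort description, PT- and subgroup-level signal scan, receptor
#' occupancy, the four-mode regression suite, the time-window and rare-PT
#' sensitivity analyses, and advisory figures. All result tables plus a
#' `manifest.json` (config echo, seed, versions) are written to
#' `config$out_dir`. Deterministic given the seed: the same config and seed
#' produce byte-identical CSVs. Any stage failure aborts the run with a
#' stage-named error and removes partial outputs.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "setup"
  tryCatch(
    {
      stage <- "ingest"
      reports <- if (inherits(config$input, "faers_config")) {
        cfg <- config$input
        cfg$seed <- config$seed
        generate_reports(cfg)
      } else {
        read_reports(config$input)
      }
      message("[ingest] ", length(unique(reports$report_id)), " reports")

      ts <- config$termset
      drugs <- config$drugs

      stage <- "cohort"
      cohort <- describe_cohort(reports, drugs, ts)
      write_table(cohort, config$out_dir, "cohort.csv")
      written <- c(written, "cohort.csv")

      stage <- "signals"
      signals <- signal_scan(reports, drugs, ts)
      message(
        "[signals] ", sum(signals$included), "/", nrow(signals),
        " drug-event pairs pass the case-count filter"
      )
      write_table(signals, config$out_dir, "signals.csv")
      written <- c(written, "signals.csv")

      stage <- "occupancy"
      occ <- occupancy_table(config$pharmacology)
      write_table(occ, config$out_dir, "occupancy.csv")
      written <- c(written, "occupancy.csv")

      stage <- "regression"
      fit <- pvpd(
        signals, occ, ts,
        mode = config$modes, exclude_drugs = config$exclude_drugs,
        median_over = config$median_over
      )
      reg <- if (is.null(fit$table)) {
        data.frame(
          receptor = character(), mode = character(), beta = numeric(),
          intercept = numeric(), p_value = numeric(), r2 = numeric(),
          n_points = integer()
        )
      } else {
        fit$table[, c("receptor", "mode", "beta", "intercept", "p_value", "r2", "n_points")]
      }
      write_table(reg, config$out_dir, "regression.csv")
      written <- c(written, "regression.csv")

      stage <- "sensitivity"
      sens <- window_scan(reports, drugs, ts, config$sensitivity$windows)
      surviving <- exclude_rare_pts(
        reports, ts, config$sensitivity$min_pt_total_reports
      )
      message(
        "[sensitivity] ", length(surviving), "/", length(sd_event_pts(ts)),
        " SD PTs survive the rare-PT filter"
      )
      if (length(surviving)) {
        rare <- signal_scan(reports, drugs, ts, level = "pt", event_pts = surviving)
        drug_rows <- lapply(drugs, function(dg) {
          tab <- build_table(reports, dg, surviving)
          r <- ror_estimate(tab)
          data.frame(
            drug = dg, analysis = "excl_rare_pt", n = tab$a,
            ror = r[["ror"]], ror_lo = r[["ror_lo"]], ror_hi = r[["ror_hi"]],
            stringsAsFactors = FALSE
          )
        })
        sens <- rbind(sens, do.call(rbind, drug_rows))
      }
      write_table(sens, config$out_dir, "sensitivity_ror.csv")
      written <- c(written, "sensitivity_ror.csv")

      stage <- "figures"
      if (!is.null(fit$table)) {
        grDevices::pdf(file.path(config$out_dir, "regression_scatter.pdf"), 10, 8)
        plot(fit)
        grDevices::dev.off()
      }

      stage <- "manifest"
      manifest <- list(
        seed = config$seed,
        drugs = drugs,
        exclude_drugs = config$exclude_drugs,
        median_over = config$median_over,
        modes = config$modes,
        input = if (inherits(config$input, "faers_config")) {
          "generated"
        } else {
          config$input
        },
        n_reports = length(unique(reports$report_id)),
        outputs = written,
        package_version = as.character(utils::packageVersion("pvpd")),
        r_version = as.character(getRversion())
      )
      jsonlite::write_json(
        manifest, file.path(config$out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      invisible(config$out_dir)
    },
    error = function(e) {
      unlink(file.path(config$out_dir, c(written, "manifest.json")))
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
}

#' A demonstration generator configuration with planted associations
#'
#' A ready-made synthetic study: the common atypical antipsychotics against
#' a dominant background drug mass, the shipped SD term set's PTs at
#' realistic background reporting rates plus non-SD background PTs, planted
#' associations (a strong iloperidone-retrograde-ejaculation pair, an
#' aripiprazole-compulsive-sexual-behavior pair, and moderate signals for
#' several other drugs) and the post-2016Q2 ICD reporting surge.
#'
#' @param n_reports dataset size, default 50000.
#' @param seed integer seed.
#' @return a `faers_config`.
#' @export
demo_faers_config <- function(n_reports = 50000, seed = 1L) {
  drugs <- c(
    background = 0.62,
    aripiprazole = 0.08, risperidone = 0.05, quetiapine = 0.05,
    olanzapine = 0.05, paliperidone = 0.04, clozapine = 0.03,
    ziprasidone = 0.02, lurasidone = 0.02, asenapine = 0.01,
    brexpiprazole = 0.01, cariprazine = 0.01, iloperidone = 0.01
  )
  ts <- default_termset()
  sd <- sd_event_pts(ts)
  pts <- c(
    stats::setNames(rep(0.002, length(sd)), sd),
    nausea = 0.05, headache = 0.04, dizziness = 0.03,
    insomnia = 0.03, "weight increased" = 0.02, somnolence = 0.02
  )
  planted <- data.frame(
    drug = c(
      "iloperidone", "aripiprazole", "aripiprazole", "aripiprazole",
      "ziprasidone", "paliperidone", "paliperidone", "risperidone",
      "quetiapine", "olanzapine"
    ),
    pt = c(
      "retrograde ejaculation", "compulsive sexual behavior",
      "psychosexual disorder", "hypersexuality",
      "erectile dysfunction", "ejaculation failure", "libido decreased",
      "libido decreased", "erectile dysfunction", "loss of libido"
    ),
    rho = c(60, 40, 20, 15, 8, 10, 6, 5, 4, 4),
    stringsAsFactors = FALSE
  )
  faers_config(
    n_reports = n_reports, drugs = drugs, pts = pts,
    planted_effects = planted,
    warning_surge = list(
      cut = "2016Q2", multiplier = 4,
      drugs = c("aripiprazole", "brexpiprazole", "cariprazine")
    ),
    icd_pts = icd_pts(ts),
    seed = seed
  )
}
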