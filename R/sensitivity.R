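#' Specification of the disproportionality sensitivity analyses
#'
#' Two analyses probe the robustness of the drug-level SD signal: a
#' time-window split around the May-2016 FDA impulse-control-disorder
#' warning (notoriety bias), and the exclusion of rare PTs (high signals
#' carried by a handful of reports). Default windows are the whole quarters
#' inside the conventional boundaries: pre-warning 2004Q1-2015Q1,
#' post-warning 2016Q3-2023Q3; receipt quarters in the 2015Q2-2016Q2 gap
#' belong to neither window.
#'
#' @param windows named list of `c(start, end)` quarter pairs; must not
#'   overlap.
#' @param min_pt_total_reports rare-PT threshold: PTs with fewer total
#'   reports than this, database-wide, are excluded (default 500; "fewer
#'   than" is strict, so a PT with exactly `min_pt_total_reports` mentions
#'   survives).
#' @param icd_exclusion whether the pipeline also reruns the scan without
#'   ICD PTs.
#' @return an object of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(windows = list(
                               pre_warning = c("2004Q1", "2015Q1"),
                               post_warning = c("2016Q3", "2023Q3")
                             ),
                             min_pt_total_reports = 500L,
                             icd_exclusion = TRUE) {
  stopifnot(min_pt_total_reports >= 0)
  idx <- lapply(windows, function(w) {
    stopifnot(length(w) == 2L)
    quarter_index(w[1]):quarter_index(w[2])
  })
  if (length(idx) > 1) {
    all_q <- unlist(idx)
    if (anyDuplicated(all_q)) stop("sensitivity windows overlap")
  }
  structure(
    list(
      windows = windows,
      min_pt_total_reports = as.integer(min_pt_total_reports),
      icd_exclusion = isTRUE(icd_exclusion)
    ),
    class = "sensitivity_spec"
  )
}

in_window <- function(quarters, window) {
  qi <- quarter_index(quarters)
  qi >= quarter_index(window[1]) & qi <= quarter_index(window[2])
}

#' Drug-level signal tables per receipt-time window
#'
#' Filters reports by receipt quarter into each window (reports in none of
#' the windows are excluded from all) and computes, per window and drug,
#' the drug-level 2x2 where the event is any SD PT, with the ROR and its
#' Woolf interval. This is the notoriety-bias sensitivity analysis: a
#' post-warning reporting surge inflates the post-window ROR relative to
#' the pre-window one.
#'
#' @param reports a `faers_reports` data frame with populated quarters.
#' @param drugs character vector of target drugs.
#' @param ts a `termset`.
#' @param windows named list of `c(start, end)` quarter pairs, default the
#'   [sensitivity_spec()] defaults.
#' @return data frame `drug, analysis, n, ror, ror_lo, ror_hi` with one row
#'   per drug x window (`n` = case count a).
#' @export
window_scan <- function(reports, drugs, ts,
                        windows = sensitivity_spec()$windows) {
  stopifnot(inherits(ts, "termset"))
  sd_pts <- sd_event_pts(ts)
  if (!length(sd_pts)) stop("term set has an empty SD event set")
  out <- list()
  for (w in names(windows)) {
    sub <- reports[in_window(reports$quarter, windows[[w]]), , drop = FALSE]
    if (nrow(sub) == 0) {
      message("window '", w, "' contains no reports")
      next
    }
    for (dg in drugs) {
      tab <- build_table(sub, dg, sd_pts)
      r <- ror_estimate(tab)
      out[[paste(w, dg)]] <- data.frame(
        drug = dg, analysis = w, n = tab$a,
        ror = r[["ror"]], ror_lo = r[["ror_lo"]], ror_hi = r[["ror_hi"]],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(
      drug = character(), analysis = character(), n = integer(),
      ror = numeric(), ror_lo = numeric(), ror_hi = numeric()
    )
  }
  rownames(res) <- NULL
  res
}

#' Drop rarely reported PTs from the SD event set
#'
#' Removes any SD PT mentioned in fewer than `min_total` reports across the
#' whole dataset (any drug, any role): rare PTs can carry extreme
#' disproportionality estimates on a handful of reports. The count is per
#' unique report, the rule is strict ("fewer than"), idempotent, and
#' independent of report order.
#'
#' @param reports a `faers_reports` data frame.
#' @param ts a `termset`.
#' @param min_total threshold, default 500.
#' @return character vector: the surviving SD PTs, for a rerun of
#'   [signal_scan()].
#' @export
exclude_rare_pts <- function(reports, ts, min_total = 500L) {
  stopifnot(inherits(ts, "termset"))
  sd_pts <- sd_event_pts(ts)
  if (min_total <= 0) return(sd_pts)
  pt_norm <- normalize_pt(reports$pt)
  keep <- pt_norm %in% sd_pts
  counts <- table(unique(data.frame(
    report_id = reports$report_id[keep], pt = pt_norm[keep]
  ))$pt)
  total <- stats::setNames(rep(0L, length(sd_pts)), sd_pts)
  total[names(counts)] <- as.integer(counts)
  sd_pts[total >= min_total]
}
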