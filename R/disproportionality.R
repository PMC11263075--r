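# Report-level preprocessing shared by the counting routines: one row per
# unique report_id with its PS drug. Rows sharing a report_id are collapsed;
# if a report carries conflicting PS drugs the last one wins (logged).
report_ps_map <- function(reports) {
  ps <- reports[reports$role == "PS", c("report_id", "drug")]
  if (nrow(ps)) {
    u <- unique(ps)
    conflict <- unique(u$report_id[duplicated(u$report_id)])
    if (length(conflict)) {
      message(
        length(conflict), " report(s) with conflicting PS drug; last entry wins"
      )
    }
    # last-wins
    u <- u[!duplicated(u$report_id, fromLast = TRUE), ]
  } else {
    u <- data.frame(report_id = character(), drug = character())
  }
  all_ids <- unique(reports$report_id)
  data.frame(
    report_id = all_ids,
    ps_drug = u$drug[match(all_ids, u$report_id)],
    stringsAsFactors = FALSE
  )
}

# unique report ids mentioning any PT in `event_pts` (any drug row, since
# reaction PTs are report-level facts repeated across drug entries)
event_report_ids <- function(reports, event_pts) {
  unique(reports$report_id[normalize_pt(reports$pt) %in% normalize_pt(event_pts)])
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Case/non-case counting under the primary-suspect rule: a report is a case
#' if its PS drug equals `drug` AND any of its reaction PTs is in
#' `event_pts`. Reports where the drug appears only with role SS, C or I
#' never count as exposed. Each report contributes exactly once; rows
#' sharing a `report_id` are collapsed first (last-wins on a conflicting PS
#' drug, with a message).
#'
#' @param reports a `faers_reports` data frame (flat long form).
#' @param drug target drug name.
#' @param event_pts character vector of PTs defining the event.
#' @return an object of class `contingency_table` with fields `a` (drug PS &
#'   event), `b` (drug PS, no event), `c` (other PS, event), `d` (neither)
#'   and `n_total`.
#' @export
build_table <- function(reports, drug, event_pts) {
  if (nrow(reports) == 0) {
    warning("empty report list: returning an all-zero table")
    return(structure(
      list(a = 0L, b = 0L, c = 0L, d = 0L, n_total = 0L, drug = drug),
      class = "contingency_table"
    ))
  }
  ps <- report_ps_map(reports)
  ev_ids <- event_report_ids(reports, event_pts)
  exposed <- !is.na(ps$ps_drug) & ps$ps_drug == drug
  has_event <- ps$report_id %in% ev_ids
  a <- sum(exposed & has_event)
  b <- sum(exposed & !has_event)
  cc <- sum(!exposed & has_event)
  d <- sum(!exposed & !has_event)
  structure(
    list(
      a = as.integer(a), b = as.integer(b), c = as.integer(cc),
      d = as.integer(d), n_total = as.integer(a + b + cc + d), drug = drug
    ),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
    dimnames = list(
      c("drug PS", "other"), c("event", "no event")
    )
  )
  cat("2x2 contingency table", if (!is.null(x$drug)) paste0("(", x$drug, ")"), "\n")
  print(m)
  invisible(x)
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' ROR = (a d)/(b c); the interval is
#' exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell leaves
#' the estimate undefined (all `NA`): no Haldane-type continuity correction
#' is applied, because silently corrected estimates would distort the
#' per-drug median RORs downstream and the case-count inclusion filter
#' already removes the tables where a correction would matter.
#'
#' @param t a `contingency_table`.
#' @return named numeric vector `c(ror, ror_lo, ror_hi)`; all `NA` if any
#'   cell is zero.
#' @export
ror_estimate <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (min(t$a, t$b, t$c, t$d) < 1) {
    return(c(ror = NA_real_, ror_lo = NA_real_, ror_hi = NA_real_))
  }
  ror <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  c(
    ror = ror,
    ror_lo = exp(log(ror) - 1.96 * se),
    ror_hi = exp(log(ror) + 1.96 * se)
  )
}

#' Information component with shrinkage lower credibility bound
#'
#' Observed-to-expected shrinkage form: with expected count
#' E = (a+b)(a+c)/n, IC = log2((a + 0.5)/(E + 0.5)), and the lower 2.5%
#' credibility bound approximated as
#' IC_025 = IC - 3.3 (a+0.5)^(-1/2) - 2.0 (a+0.5)^(-3/2). The +0.5
#' shrinkage keeps the estimate finite at zero observed counts and pulls
#' small-count signals toward zero.
#'
#' @param t a `contingency_table` with `n_total > 0`.
#' @return named numeric vector `c(ic, ic_lo)` in bits.
#' @export
ic_estimate <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$n_total <= 0) stop("empty table: IC undefined")
  e <- (t$a + t$b) * (t$a + t$c) / t$n_total
  ic <- log2((t$a + 0.5) / (e + 0.5))
  ic_lo <- ic - 3.3 * (t$a + 0.5)^(-0.5) - 2.0 * (t$a + 0.5)^(-1.5)
  c(ic = ic, ic_lo = ic_lo)
}

#' Case-count inclusion filter
#'
#' A drug-PT pair enters the analysis only when its case count exceeds 3,
#' i.e. a >= 4 (strict reading of "greater than 3").
#'
#' @param t a `contingency_table`.
#' @return logical.
#' @export
include_pt <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  t$a >= 4L
}

#' Scan all drug-PT and drug-subgroup pairs for disproportionality signals
#'
#' Computes, for every drug and every SD PT of the term set (and every
#' symptom subgroup at `level = "subgroup"`), the 2x2 table under the
#' primary-suspect rule, the ROR with Woolf interval, the shrinkage IC with
#' its lower bound, significance flags (`ror_lo > 1`, `ic_lo > 0`) and the
#' case-count inclusion flag. A report with several PTs of the same
#' subgroup counts once for that subgroup; with PTs in different subgroups
#' it counts once in each.
#'
#' @param reports a `faers_reports` data frame.
#' @param drugs character vector of target drugs.
#' @param ts a `termset`; its SD event PTs define the scanned PT list.
#' @param level `"both"` (default), `"pt"` or `"subgroup"`.
#' @param event_pts optional character vector restricting the scanned PTs
#'   (e.g. after [exclude_rare_pts()] or ICD-PT exclusion); default all SD
#'   PTs of the term set.
#' @return data frame with one row per drug x event:
#'   `drug, event, level, a, b, c, d, ror, ror_lo, ror_hi, ic, ic_lo,
#'   significant_ror, significant_ic, included`.
#' @export
signal_scan <- function(reports, drugs, ts, level = c("both", "pt", "subgroup"),
                        event_pts = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(ts, "termset"))
  sd_pts <- sd_event_pts(ts)
  if (length(sd_pts) == 0) stop("term set has an empty SD event set; refusing to scan")
  if (!is.null(event_pts)) sd_pts <- intersect(sd_pts, normalize_pt(event_pts))
  if (length(sd_pts) == 0) stop("no SD PTs left to scan after restriction")

  ps <- report_ps_map(reports)
  n_total <- nrow(ps)
  pt_norm <- normalize_pt(reports$pt)

  # unique (report, pt) incidences over the scanned SD PTs
  keep <- pt_norm %in% sd_pts
  inc <- unique(data.frame(
    report_id = reports$report_id[keep], pt = pt_norm[keep],
    stringsAsFactors = FALSE
  ))
  inc$ps_drug <- ps$ps_drug[match(inc$report_id, ps$report_id)]

  scan_events <- function(inc_ev, events, lev) {
    # inc_ev: unique (report_id, event, ps_drug)
    n_event <- table(factor(inc_ev$event, levels = events))
    n_ps <- table(factor(ps$ps_drug, levels = drugs))
    in_target <- !is.na(inc_ev$ps_drug) & inc_ev$ps_drug %in% drugs
    a_tab <- table(
      factor(inc_ev$ps_drug[in_target], levels = drugs),
      factor(inc_ev$event[in_target], levels = events)
    )
    out <- vector("list", length(drugs) * length(events))
    k <- 0L
    for (dg in drugs) {
      for (ev in events) {
        a <- as.integer(a_tab[dg, ev])
        b <- as.integer(n_ps[[dg]]) - a
        cc <- as.integer(n_event[[ev]]) - a
        dd <- n_total - a - b - cc
        tab <- structure(
          list(a = a, b = b, c = cc, d = dd, n_total = n_total, drug = dg),
          class = "contingency_table"
        )
        r <- ror_estimate(tab)
        ic <- ic_estimate(tab)
        k <- k + 1L
        out[[k]] <- data.frame(
          drug = dg, event = ev, level = lev,
          a = a, b = b, c = cc, d = dd,
          ror = r[["ror"]], ror_lo = r[["ror_lo"]], ror_hi = r[["ror_hi"]],
          ic = ic[["ic"]], ic_lo = ic[["ic_lo"]],
          significant_ror = !is.na(r[["ror_lo"]]) && r[["ror_lo"]] > 1,
          significant_ic = ic[["ic_lo"]] > 0,
          included = a >= 4L,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  }

  res <- list()
  if (level %in% c("both", "pt")) {
    inc_pt <- inc
    names(inc_pt)[names(inc_pt) == "pt"] <- "event"
    res$pt <- scan_events(inc_pt, sd_pts, "pt")
  }
  if (level %in% c("both", "subgroup")) {
    sub_of <- stats::setNames(ts$table$subgroup, ts$table$pt)
    inc_sub <- inc
    inc_sub$event <- unname(sub_of[inc_sub$pt])
    inc_sub <- unique(inc_sub[inc_sub$event %in% SD_SUBGROUPS,
                              c("report_id", "event", "ps_drug")])
    res$subgroup <- scan_events(inc_sub, SD_SUBGROUPS, "subgroup")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-drug median reporting odds ratio
#'
#' The summary feeding the occupancy regression: the median of the drug's
#' PT-level RORs over pairs passing the case-count filter (even-count median
#' = midpoint of the two central values). Undefined estimates (zero cells)
#' are dropped with a message; a drug with no usable estimate returns `NA`
#' with a message, and is dropped from regressions by the caller.
#'
#' @param signals output of [signal_scan()].
#' @param drug drug name.
#' @param over `"included"` (default: all pairs passing the count filter) or
#'   `"significant"` (only pairs additionally flagged by ROR).
#' @return the median ROR, or `NA` if the drug has no usable estimates.
#' @export
median_ror <- function(signals, drug, over = c("included", "significant")) {
  over <- match.arg(over)
  s <- signals[signals$level == "pt" & signals$drug == drug & signals$included, ]
  if (over == "significant") s <- s[s$significant_ror, ]
  if (any(is.na(s$ror))) {
    message(
      sum(is.na(s$ror)), " undefined ROR estimate(s) dropped from the median for ", drug
    )
    s <- s[!is.na(s$ror), ]
  }
  if (nrow(s) == 0) {
    message("no included PT-level estimate for ", drug, "; excluded from regression")
    return(NA_real_)
  }
  stats::median(s$ror)
}
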