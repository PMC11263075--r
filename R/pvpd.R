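PVPD_MODES <- c("main", "activity_signed", "pki", "excl_icd_activity_signed")

predictor_kind_of <- function(mode) {
  switch(mode,
    main = "occupancy",
    activity_signed = "signed_occupancy",
    pki = "pki",
    excl_icd_activity_signed = "occupancy_excl_icd"
  )
}

#' Receptors with enough occupancy data to fit
#'
#' A receptor enters the regression only with at least three non-missing
#' per-drug predictor values.
#'
#' @param occ an `occupancy_table` data frame.
#' @param min_n minimum number of drugs per receptor, default 3.
#' @param column predictor column to count, default `"occupancy_pct"`.
#' @return character vector of eligible receptor names.
#' @export
eligible_receptors <- function(occ, min_n = 3L, column = "occupancy_pct") {
  if (nrow(occ) == 0) return(character())
  n <- tapply(!is.na(occ[[column]]), occ$receptor, sum)
  names(n)[!is.na(n) & n >= min_n]
}

#' Ordinary least squares of median ROR on one receptor's predictor
#'
#' Fits y ~ x by OLS (via [stats::lm()]): slope beta = cov(x,y)/var(x),
#' two-sided p for slope = 0 from the t distribution on n - 2 degrees of
#' freedom, R^2 = squared Pearson correlation.
#'
#' @param x per-drug predictor values (occupancy, signed occupancy or pKi).
#' @param y per-drug median RORs.
#' @param receptor,predictor_kind labels carried into the result.
#' @return a list of class `pvpd_lm`: the fit summary row (`receptor`,
#'   `predictor_kind`, `beta`, `intercept`, `p_value`, `r2`, `n_points`),
#'   the underlying `lm` object, and the fitting data.
#' @export
fit_univariate <- function(x, y, receptor = NA_character_,
                           predictor_kind = "occupancy") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points, got ", n)
  if (stats::var(x) == 0) stop("degenerate predictor: x is constant")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  if (stats::var(y) == 0) {
    # flat response: slope 0, no explained variance, no evidence against it
    beta <- 0; p <- 1; r2 <- 0
  } else {
    # an exact fit makes summary.lm warn about near-zero residual variance;
    # that case is legitimate here (noiseless synthetic data) and handled
    # by the p clamp below
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    beta <- unname(cf[["x"]])
    p <- sm$coefficients["x", "Pr(>|t|)"]
    # an exactly collinear fit has zero residual SE; keep p inside (0, 1]
    p <- max(min(p, 1), .Machine$double.xmin)
    r2 <- sm$r.squared
  }
  structure(
    list(
      receptor = receptor, predictor_kind = predictor_kind,
      beta = beta, intercept = unname(cf[[1]]), p_value = p, r2 = r2,
      n_points = n, lm = fit,
      data = data.frame(x = x, y = y)
    ),
    class = "pvpd_lm"
  )
}

#' @export
print.pvpd_lm <- function(x, ...) {
  cat(sprintf(
    "pvpd OLS [%s ~ %s]: beta = %.4g, intercept = %.4g, p = %.3g, R2 = %.3f, n = %d\n",
    "median ROR", x$predictor_kind, x$beta, x$intercept, x$p_value, x$r2,
    x$n_points
  ))
  invisible(x)
}

# per-drug median RORs as a named vector, NA drugs dropped
drug_median_rors <- function(signals, drugs, over, event_pts_keep = NULL) {
  if (!is.null(event_pts_keep)) {
    signals <- signals[signals$level != "pt" |
      signals$event %in% normalize_pt(event_pts_keep), ]
  }
  y <- vapply(drugs, function(d) median_ror(signals, d, over = over), numeric(1))
  y[!is.na(y)]
}

#' Fit the pharmacovigilance-pharmacodynamic regression suite
#'
#' The package's central model: for each receptor with at least
#' `min_points` drugs, an ordinary least-squares regression of the per-drug
#' median reporting odds ratio (the pharmacovigilance signal strength) on a
#' per-receptor pharmacodynamic predictor. Modes:
#' \describe{
#'   \item{`main`}{predictor = receptor occupancy (percent).}
#'   \item{`activity_signed`}{predictor = occupancy with the sign reversed
#'     for antagonists/inverse agonists; drugs of unknown activity are
#'     dropped.}
#'   \item{`pki`}{predictor = pKi, sidestepping multi-source concentration
#'     inputs.}
#'   \item{`excl_icd_activity_signed`}{median RORs recomputed after removing
#'     the impulse-control-disorder PTs (notoriety-prone terms), then the
#'     activity-signed fit.}
#' }
#'
#' @param signals a [signal_scan()] result.
#' @param occ an `occupancy_table` from [occupancy_table()].
#' @param ts a `termset`; required for mode `excl_icd_activity_signed`.
#' @param mode one or more of the modes above; default all four.
#' @param exclude_drugs drugs removed from the regression inputs (default
#'   `"iloperidone"`, whose small report base distorts signal estimates).
#' @param median_over passed to [median_ror()].
#' @param min_points minimum drugs per receptor, default 3; receptors
#'   falling below it in a given mode are dropped with a message.
#' @param log_ror if `TRUE`, regress log(median ROR) instead.
#' @return an object of class `pvpd_fit`.
#' @export
pvpd <- function(signals, occ, ts = NULL, mode = PVPD_MODES,
                 exclude_drugs = "iloperidone",
                 median_over = c("included", "significant"),
                 min_points = 3L, log_ror = FALSE) {
  mode <- match.arg(mode, PVPD_MODES, several.ok = TRUE)
  median_over <- match.arg(median_over)
  if ("excl_icd_activity_signed" %in% mode && is.null(ts)) {
    stop("mode 'excl_icd_activity_signed' needs the term set (ts)")
  }
  occ <- occ[!occ$drug %in% exclude_drugs, ]
  drugs <- setdiff(unique(signals$drug), exclude_drugs)

  y_all <- drug_median_rors(signals, drugs, median_over)
  fits <- list()
  data_used <- list()
  for (m in mode) {
    pred_col <- switch(m,
      main = "occupancy_pct",
      activity_signed = "signed_occupancy",
      pki = "pki",
      excl_icd_activity_signed = "signed_occupancy"
    )
    y <- if (m == "excl_icd_activity_signed") {
      keep_pts <- setdiff(sd_event_pts(ts), icd_pts(ts))
      drug_median_rors(signals, drugs, median_over, event_pts_keep = keep_pts)
    } else {
      y_all
    }
    if (log_ror) y <- log(y)
    for (rec in sort(unique(occ$receptor))) {
      o <- occ[occ$receptor == rec, ]
      x <- stats::setNames(o[[pred_col]], o$drug)
      common <- intersect(names(x)[!is.na(x)], names(y))
      if (length(common) < min_points) {
        message(
          "receptor ", rec, " dropped in mode '", m, "': only ",
          length(common), " usable drug(s)"
        )
        next
      }
      f <- fit_univariate(
        x[common], y[common],
        receptor = rec, predictor_kind = predictor_kind_of(m)
      )
      f$mode <- m
      f$drugs <- common
      fits[[paste(m, rec, sep = ".")]] <- f
    }
  }
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      receptor = f$receptor, mode = f$mode, beta = f$beta,
      intercept = f$intercept, p_value = f$p_value, r2 = f$r2,
      n_points = f$n_points, stringsAsFactors = FALSE
    )
  }))
  if (!is.null(tab)) rownames(tab) <- NULL
  structure(
    list(
      fits = fits, table = tab, modes = mode,
      median_over = median_over, exclude_drugs = exclude_drugs,
      log_ror = log_ror, median_ror = y_all
    ),
    class = "pvpd_fit"
  )
}

#' @export
print.pvpd_fit <- function(x, digits = 4, ...) {
  cat("Pharmacovigilance-pharmacodynamic regression suite\n")
  cat(
    "  response: ", if (x$log_ror) "log " else "",
    "median ROR over ", x$median_over, " PTs; excluded drug(s): ",
    paste(x$exclude_drugs, collapse = ", "), "\n\n",
    sep = ""
  )
  if (is.null(x$table)) {
    cat("  (no receptor had enough data to fit)\n")
  } else {
    print(format(x$table, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a PV-PD regression suite
#'
#' @param object a `pvpd_fit`.
#' @param alpha significance level for the slope test.
#' @param p_adjust if `TRUE`, adds Benjamini-Hochberg adjusted p-values
#'   (across receptors, within each mode) as an extra column; the primary
#'   raw p-values are unchanged.
#' @param ... unused.
#' @export
summary.pvpd_fit <- function(object, alpha = 0.05, p_adjust = FALSE, ...) {
  tab <- object$table
  if (!is.null(tab)) {
    tab$significant <- tab$p_value < alpha
    if (isTRUE(p_adjust)) {
      tab$p_bh <- stats::ave(tab$p_value, tab$mode,
        FUN = function(p) stats::p.adjust(p, method = "BH")
      )
    }
  }
  structure(
    list(table = tab, alpha = alpha, n_drugs = length(object$median_ror)),
    class = "summary.pvpd_fit"
  )
}

#' @export
print.summary.pvpd_fit <- function(x, ...) {
  cat(
    "PV-PD regression summary (", x$n_drugs, " drugs with a median ROR; ",
    "slope test at alpha = ", x$alpha, ")\n",
    sep = ""
  )
  if (is.null(x$table)) {
    cat("no fits\n")
    return(invisible(x))
  }
  print(format(x$table, digits = 4), row.names = FALSE)
  sig <- x$table[x$table$significant, ]
  if (nrow(sig)) {
    cat(
      "significant receptor association(s): ",
      paste(paste0(sig$receptor, " [", sig$mode, "]"), collapse = ", "), "\n",
      sep = ""
    )
  } else {
    cat("no receptor association reaches significance\n")
  }
  invisible(x)
}

#' @export
coef.pvpd_fit <- function(object, ...) {
  if (is.null(object$table)) return(NULL)
  m <- as.matrix(object$table[, c("intercept", "beta")])
  rownames(m) <- paste(object$table$mode, object$table$receptor, sep = ".")
  m
}

#' @export
residuals.pvpd_fit <- function(object, ...) {
  lapply(object$fits, function(f) stats::residuals(f$lm))
}

#' Predict median ROR from predictor values
#'
#' @param object a `pvpd_fit`.
#' @param receptor receptor name.
#' @param mode which fitted mode to use (default the first fitted).
#' @param newdata numeric vector of predictor values; default the fitting
#'   values.
#' @param ... unused.
#' @return predicted (log) median RORs.
#' @export
predict.pvpd_fit <- function(object, receptor, mode = object$modes[1],
                             newdata = NULL, ...) {
  key <- paste(mode, receptor, sep = ".")
  f <- object$fits[[key]]
  if (is.null(f)) stop("no fit for receptor ", receptor, " in mode ", mode)
  if (is.null(newdata)) {
    stats::predict(f$lm)
  } else {
    stats::predict(f$lm, newdata = data.frame(x = newdata))
  }
}

#' Scatter plots of the receptor regressions
#'
#' One panel per fitted receptor x mode: drug-labelled points with the OLS
#' line.
#'
#' @param x a `pvpd_fit`.
#' @param mode which mode(s) to draw, default all fitted.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pvpd_fit <- function(x, mode = x$modes, ...) {
  fits <- Filter(function(f) f$mode %in% mode, x$fits)
  if (!length(fits)) {
    warning("nothing to plot")
    return(invisible(x))
  }
  nf <- length(fits)
  nc <- ceiling(sqrt(nf))
  old <- graphics::par(mfrow = c(ceiling(nf / nc), nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (f in fits) {
    graphics::plot(
      f$data$x, f$data$y,
      xlab = f$predictor_kind, ylab = "median ROR",
      main = sprintf("%s (%s): p=%.3g, R2=%.2f", f$receptor, f$mode, f$p_value, f$r2),
      pch = 19, ...
    )
    graphics::abline(f$lm, lty = 2)
    graphics::text(f$data$x, f$data$y, labels = f$drugs, pos = 3, cex = 0.6)
  }
  invisible(x)
}
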