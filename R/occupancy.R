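RECEPTORS <- c(
  "5-HT1A", "5-HT2A", "5-HT2C", "5-HT7",
  "alpha1", "alpha2", "muscarinic", "D2", "D3", "H1"
)

ACTIVITIES <- c(
  "full_agonist", "partial_agonist", "antagonist",
  "inverse_agonist", "unspecified"
)

check_positive <- function(x, field) {
  if (any(!is.finite(x) | x <= 0)) stop("'", field, "' must be strictly positive")
  invisible(x)
}

#' Unbound drug concentration from therapeutic level and free fraction
#'
#' C_U = 1000 * F_U * C_T / MW, giving nmol/L: C_T in ng/mL (equivalently
#' ug/L, the unit therapeutic-drug-monitoring ranges are published in)
#' divided by the molecular weight in g/mol gives umol/m3 = nmol/L after
#' the factor 1000.
#'
#' @param f_u unbound fraction in (0, 1].
#' @param c_t_ng_per_ml total therapeutic concentration, ng/mL (upper bound
#'   of the recommended range).
#' @param mw_g_per_mol molecular weight, g/mol.
#' @return unbound concentration in nM.
#' @export
unbound_concentration <- function(f_u, c_t_ng_per_ml, mw_g_per_mol) {
  check_positive(f_u, "f_u")
  if (any(f_u > 1)) stop("'f_u' must lie in (0, 1]")
  check_positive(c_t_ng_per_ml, "c_t_ng_per_ml")
  check_positive(mw_g_per_mol, "mw_g_per_mol")
  1000 * f_u * c_t_ng_per_ml / mw_g_per_mol
}

#' Receptor occupancy from unbound concentration and Ki
#'
#' Single-site competitive binding: occupancy (%) = 100 * C_U / (Ki + C_U).
#' Scale-invariant (multiplying both C_U and Ki by the same factor leaves
#' occupancy unchanged), strictly increasing in C_U, strictly decreasing in
#' Ki, 50% at C_U = Ki, and asymptotically (never exactly) 100%.
#'
#' @param c_u_nM unbound concentration, nM.
#' @param ki_nM inhibition constant, nM.
#' @return occupancy in percent, in (0, 100).
#' @export
occupancy_pct <- function(c_u_nM, ki_nM) {
  check_positive(c_u_nM, "c_u_nM")
  check_positive(ki_nM, "ki_nM")
  100 * c_u_nM / (ki_nM + c_u_nM)
}

#' Activity-signed occupancy
#'
#' For the regression sensitivity analysis distinguishing pharmacological
#' direction: antagonists and inverse agonists get a reversed sign (an
#' agonist and an antagonist with identical affinity act oppositely);
#' drugs with unknown activity are returned as `NA` and excluded from the
#' activity-signed models.
#'
#' @param occ_pct occupancy in \[0, 100\].
#' @param activity one of `"full_agonist"`, `"partial_agonist"`,
#'   `"antagonist"`, `"inverse_agonist"`, `"unspecified"`.
#' @return signed occupancy in \[-100, 100\], or `NA` for unspecified
#'   activity.
#' @export
signed_occupancy <- function(occ_pct, activity) {
  stopifnot(all(occ_pct >= 0 & occ_pct <= 100))
  activity <- match.arg(activity, ACTIVITIES, several.ok = TRUE)
  sgn <- ifelse(
    activity %in% c("antagonist", "inverse_agonist"), -1,
    ifelse(activity %in% c("full_agonist", "partial_agonist"), 1, NA_real_)
  )
  sgn * occ_pct
}

#' pKi from Ki in nM
#'
#' Standard molar convention: pKi = -log10(Ki in mol/L) = 9 - log10(Ki in
#' nM). Used as an occupancy substitute in the regression sensitivity
#' analysis that avoids propagating multi-source concentration data.
#'
#' @param ki_nM inhibition constant, nM.
#' @return pKi (dimensionless).
#' @export
pki <- function(ki_nM) {
  check_positive(ki_nM, "ki_nM")
  9 - log10(ki_nM)
}

#' Read a drug x receptor pharmacology table
#'
#' Expects columns `drug, receptor, ki_nM, activity, f_u, c_t_ng_per_ml,
#' mw_g_per_mol` (a `source` provenance column is carried through if
#' present). Duplicate drug x receptor rows are collapsed to the geometric
#' mean Ki (binding constants span orders of magnitude) with a message.
#' Muscarinic and adrenergic receptors are single pseudo-receptors,
#' irrespective of subtype.
#'
#' @param path CSV path.
#' @return validated data frame of class `pharmacology`.
#' @export
read_pharmacology <- function(path) {
  if (!file.exists(path)) stop("pharmacology file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(
    "drug", "receptor", "ki_nM", "activity", "f_u",
    "c_t_ng_per_ml", "mw_g_per_mol"
  )
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("pharmacology table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(df$receptor), RECEPTORS)
  if (length(bad)) stop("unknown receptor(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$activity), ACTIVITIES)
  if (length(bad)) stop("unknown activity class(es): ", paste(bad, collapse = ", "))
  check_positive(df$ki_nM, "ki_nM")
  check_positive(df$c_t_ng_per_ml, "c_t_ng_per_ml")
  check_positive(df$mw_g_per_mol, "mw_g_per_mol")
  if (any(df$f_u <= 0 | df$f_u > 1)) stop("'f_u' must lie in (0, 1]")

  key <- paste(df$drug, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    message(
      length(dup_keys),
      " duplicated drug x receptor entr(ies) collapsed to geometric-mean Ki"
    )
    ki_gm <- tapply(df$ki_nM, key, function(x) exp(mean(log(x))))
    df <- df[!duplicated(key), ]
    df$ki_nM <- unname(ki_gm[paste(df$drug, df$receptor, sep = "\r")])
  }
  rownames(df) <- NULL
  class(df) <- c("pharmacology", "data.frame")
  df
}

#' The synthetic demonstration pharmacology table shipped with the package
#'
#' Plausible order-of-magnitude binding constants, unbound fractions,
#' therapeutic-range upper bounds and molecular weights for the common
#' atypical antipsychotics across ten receptors. The values are synthetic
#' demonstration data (see the `source` column) — not asserted to equal any
#' published Ki snapshot; substitute a curated table for real analyses.
#'
#' @return a `pharmacology` data frame.
#' @export
demo_pharmacology <- function() {
  read_pharmacology(
    system.file("extdata", "pharmacology_synthetic.csv", package = "pvpd")
  )
}

#' Per drug x receptor occupancy table
#'
#' Applies [unbound_concentration()], [occupancy_pct()],
#' [signed_occupancy()] and [pki()] row-wise to a pharmacology table.
#'
#' @param pharm a `pharmacology` data frame from [read_pharmacology()].
#' @return data frame `drug, receptor, c_u_nM, occupancy_pct,
#'   signed_occupancy, pki` of class `occupancy_table`.
#' @export
occupancy_table <- function(pharm) {
  stopifnot(inherits(pharm, "data.frame"))
  needed <- c("drug", "receptor", "ki_nM", "activity", "f_u", "c_t_ng_per_ml", "mw_g_per_mol")
  missing_cols <- setdiff(needed, names(pharm))
  if (length(missing_cols)) {
    stop("pharmacology table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  c_u <- unbound_concentration(pharm$f_u, pharm$c_t_ng_per_ml, pharm$mw_g_per_mol)
  occ <- occupancy_pct(c_u, pharm$ki_nM)
  out <- data.frame(
    drug = pharm$drug,
    receptor = pharm$receptor,
    c_u_nM = c_u,
    occupancy_pct = occ,
    signed_occupancy = signed_occupancy(occ, pharm$activity),
    pki = pki(pharm$ki_nM),
    stringsAsFactors = FALSE
  )
  class(out) <- c("occupancy_table", "data.frame")
  out
}
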