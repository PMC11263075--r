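#' @keywords internal
"_PACKAGE"

# The two MedDRA high-level group terms whose member PTs constitute the
# sexual-dysfunction (SD) event set.
SD_HLGTS <- c(
  "sexual function and fertility disorders",
  "sexual dysfunctions, disturbances and gender identity disorders"
)

SD_SUBGROUPS <- c(
  "hypersexuality", "hyposexuality",
  "erectile_dysfunction", "ejaculatory_dysfunction"
)

#' Normalize a preferred-term string
#'
#' Lower-cases and collapses internal whitespace. All PT matching in the
#' package is case-insensitive after whitespace normalization, because
#' spontaneous-report PT casing is inconsistent across database eras.
#'
#' @param x character vector of PT strings.
#' @return normalized character vector.
#' @export
normalize_pt <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Construct a term set
#'
#' A term set is the MedDRA-like vocabulary driving the analysis: preferred
#' terms (PTs), their high-level group term (HLGT), their symptom subgroup
#' (one of hypersexuality, hyposexuality, erectile_dysfunction,
#' ejaculatory_dysfunction, or none), and a flag marking the
#' impulse-control-disorder (ICD) related PTs used by the notoriety-bias
#' sensitivity analyses.
#'
#' @param df data frame with columns `pt`, `hlgt`, `subgroup`, `icd_flag`.
#' @return an object of class `termset`.
#' @details Duplicate PT rows with identical mappings are collapsed; rows with
#'   conflicting mappings are an error naming the PT. A subgroup assignment
#'   is only allowed for PTs whose HLGT is one of the two SD HLGTs, so the
#'   four subgroup sets are always disjoint subsets of [sd_event_pts()].
#' @export
termset <- function(df) {
  needed <- c("pt", "hlgt", "subgroup", "icd_flag")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("term-set table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, needed]
  df$pt <- normalize_pt(df$pt)
  df$hlgt <- normalize_pt(df$hlgt)
  df$subgroup <- tolower(trimws(as.character(df$subgroup)))
  df$icd_flag <- as.integer(df$icd_flag)

  bad_sub <- setdiff(unique(df$subgroup), c(SD_SUBGROUPS, "none"))
  if (length(bad_sub)) {
    stop("unknown subgroup label(s): ", paste(bad_sub, collapse = ", "))
  }
  if (any(is.na(df$icd_flag)) || any(!df$icd_flag %in% c(0L, 1L))) {
    stop("icd_flag must be 0 or 1")
  }

  # collapse exact duplicates, reject conflicting ones
  df <- unique(df)
  dup <- df$pt[duplicated(df$pt)]
  if (length(dup)) {
    stop(
      "conflicting mappings for PT(s): ",
      paste(unique(dup), collapse = ", ")
    )
  }
  off_sd <- df$pt[df$subgroup != "none" & !(df$hlgt %in% SD_HLGTS)]
  if (length(off_sd)) {
    stop(
      "subgroup assigned to PT(s) outside the SD HLGTs: ",
      paste(off_sd, collapse = ", ")
    )
  }
  rownames(df) <- NULL
  structure(list(table = df), class = "termset")
}

#' Read a term set from CSV
#'
#' @param path CSV file with header `pt,hlgt,subgroup,icd_flag`.
#' @return a [termset()] object (possibly empty; downstream stages refuse to
#'   run on an empty term set).
#' @export
read_termset <- function(path) {
  if (!file.exists(path)) stop("term-set file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(
      pt = character(), hlgt = character(),
      subgroup = character(), icd_flag = integer()
    )
  }
  termset(df)
}

#' Write a term set to CSV
#'
#' Round-trips with [read_termset()]: reading the written file reproduces an
#' equivalent mapping.
#'
#' @param ts a `termset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_termset <- function(ts, path) {
  stopifnot(inherits(ts, "termset"))
  utils::write.csv(ts$table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The default SD term set shipped with the package
#'
#' Built from the sexual-dysfunction PTs named in the primary literature on
#' antipsychotic-associated sexual dysfunction (retrograde ejaculation,
#' compulsive sexual behavior, hypersexuality, excessive masturbation, libido
#' increased/decreased, psychosexual disorder, erectile dysfunction,
#' ejaculation failure, priapism, anorgasmia, ...). It is an approximation:
#' the full licensed MedDRA 26.0 PT list under the two SD HLGTs is not
#' redistributable, and every analysis function takes the term set as an
#' argument so users can substitute the real one.
#'
#' @return a `termset`.
#' @export
default_termset <- function() {
  read_termset(system.file("extdata", "termset.csv", package = "pvpd"))
}

#' SD event PTs of a term set
#'
#' Exactly the PTs whose HLGT is one of the two sexual-dysfunction HLGTs.
#' Note the bare PT "sexual dysfunction" is itself one member term of the
#' event set, distinct from the SD umbrella the analysis targets.
#'
#' @param ts a `termset`.
#' @return character vector of normalized PTs.
#' @export
sd_event_pts <- function(ts) {
  stopifnot(inherits(ts, "termset"))
  ts$table$pt[ts$table$hlgt %in% SD_HLGTS]
}

#' PTs belonging to one symptom subgroup
#'
#' @param ts a `termset`.
#' @param subgroup one of `"hypersexuality"`, `"hyposexuality"`,
#'   `"erectile_dysfunction"`, `"ejaculatory_dysfunction"`.
#' @return character vector of member PTs.
#' @export
subgroup_pts <- function(ts, subgroup) {
  stopifnot(inherits(ts, "termset"))
  subgroup <- match.arg(subgroup, SD_SUBGROUPS)
  ts$table$pt[ts$table$subgroup == subgroup]
}

#' Impulse-control-disorder related PTs
#'
#' The PTs swept into the May-2016 FDA impulse-control-disorder warning
#' (compulsive sexual behavior, hypersexuality, excessive masturbation,
#' libido increased); used by the notoriety-bias sensitivity analyses.
#'
#' @param ts a `termset`.
#' @return character vector of PTs.
#' @export
icd_pts <- function(ts) {
  stopifnot(inherits(ts, "termset"))
  ts$table$pt[ts$table$icd_flag == 1L]
}

#' @export
print.termset <- function(x, ...) {
  cat(
    "Term set:", nrow(x$table), "PTs;",
    length(sd_event_pts(x)), "in the SD event set;",
    length(icd_pts(x)), "ICD-related\n"
  )
  tab <- table(factor(x$table$subgroup, levels = c(SD_SUBGROUPS, "none")))
  cat("subgroups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
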