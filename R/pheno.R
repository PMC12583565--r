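#' Round a prevalence percentage
#'
#' Percentages are rounded half away from zero to the nearest integer,
#' except exact half-integers (e.g. 87.5), which are reported with one
#' decimal -- the convention of clinical prevalence tables that print
#' "35 (87.5)".
#'
#' @param p Percentage value(s).
#' @return Rounded value(s).
#' @export
round_percent <- function(p) {
  half <- abs(p * 2 - round(p * 2)) < 1e-9 & abs(p - round(p)) > 1e-9
  ifelse(half, round(p, 1L), sign(p) * floor(abs(p) + 0.5))
}

.series_subset <- function(phenotype_table, series) {
  series <- match.arg(series, c("this_series", "literature", "total"))
  if (series == "total") phenotype_table
  else phenotype_table[phenotype_table$series == series, , drop = FALSE]
}

#' Prevalence of a clinical feature with explicit denominators
#'
#' Counts responders (individuals with a non-unknown state) as the
#' denominator and affected (`present`) individuals as the numerator;
#' `unknown` never enters either. Zero responders yields `percent = NA`
#' with a warning rather than an error, so tables with sparse features
#' still render.
#'
#' @param phenotype_table Validated phenotype table.
#' @param feature Feature column name.
#' @param series `"this_series"`, `"literature"` or `"total"`.
#' @return One-row data frame `feature_name`, `series`, `n_affected`,
#'   `n_responders`, `percent`.
#' @export
prevalence <- function(phenotype_table, feature, series = "total") {
  if (!feature %in% names(phenotype_table))
    stop("unknown feature: ", feature)
  sub <- .series_subset(phenotype_table, series)
  v <- sub[[feature]]
  n_resp <- sum(v != "unknown")
  n_aff <- sum(v == "present")
  pct <- if (n_resp == 0L) {
    warning("feature '", feature, "' has zero responders in ", series)
    NA_real_
  } else round_percent(100 * n_aff / n_resp)
  data.frame(feature_name = feature, series = series,
             n_affected = n_aff, n_responders = n_resp, percent = pct,
             stringsAsFactors = FALSE)
}

#' Merge two phenotype series
#'
#' Concatenates per-individual tables (e.g. a new series and a literature
#' review) while preserving series labels; feature columns absent from one
#' table are filled with `unknown`. Individual ids must be disjoint.
#'
#' @param table_a,table_b Phenotype tables.
#' @return Merged, validated phenotype table.
#' @export
merge_series <- function(table_a, table_b) {
  if (nrow(table_a) == 0L) return(table_b)
  if (nrow(table_b) == 0L) return(table_a)
  clash <- intersect(table_a$individual_id, table_b$individual_id)
  if (length(clash))
    stop("individual id collision: ", paste(clash[1L], collapse = ", "))
  feats <- union(names(table_a), names(table_b))
  fill <- function(x) {
    for (f in setdiff(feats, names(x))) x[[f]] <- "unknown"
    x[, feats, drop = FALSE]
  }
  out <- rbind(fill(table_a), fill(table_b))
  rownames(out) <- NULL
  validate_phenotype_table(out)
  out
}

#' Clinical summary table across series
#'
#' For each feature, emits prevalence rows for the new series, the
#' literature, and their total, in input feature order.
#'
#' @param phenotype_table Validated phenotype table.
#' @param feature_list Feature column names.
#' @return Data frame of [prevalence()] rows.
#' @export
table_one <- function(phenotype_table, feature_list) {
  rows <- lapply(feature_list, function(f)
    do.call(rbind, lapply(c("this_series", "literature", "total"),
                          function(s) prevalence(phenotype_table, f, s))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
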