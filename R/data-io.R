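SAMPLE_ROLES <- c("case", "control", "other_disorder", "test")
PHENO_STATES <- c("present", "absent", "unknown")
MODEL_SCHEMA_VERSION <- 1L

.delim <- function(dialect) {
  dialect <- match.arg(dialect, c("tsv", "csv"))
  if (dialect == "tsv") "\t" else ","
}

#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation fractions with
#' unique probe ids as rownames and unique sample ids as colnames. Values
#' must lie in \[0, 1\]; `NA` marks a missing measurement.
#'
#' @param x Numeric matrix to validate.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending probe/sample cell.
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate probe ids: ", rownames(x)[duplicated(rownames(x))][1L])
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ", colnames(x)[duplicated(colnames(x))][1L])
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]],
      x[bad[1L, 1L], bad[1L, 2L]]))
  }
  invisible(x)
}

#' Read a beta-value matrix
#'
#' First column holds probe ids, header row holds sample ids. Out-of-range
#' values are an error, never clamped; `NA` encodes missing betas.
#'
#' @param path File to read.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, dialect = "tsv") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim(dialect),
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("beta matrix file needs a probe column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate probe ids in ", path, ": ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric beta values in ", path)
  rownames(m) <- ids
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix
#'
#' @param x Validated beta matrix.
#' @param path Output file.
#' @param dialect `"tsv"` or `"csv"`.
#' @param digits Significant digits retained (round-trip stable at 6).
#' @export
write_beta_matrix <- function(x, path, dialect = "tsv", digits = 6L) {
  validate_beta_matrix(x)
  df <- data.frame(probe_id = rownames(x),
                   signif(x, digits), check.names = FALSE)
  utils::write.table(df, path, sep = .delim(dialect), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' Required columns: `sample_id`, `role` (one of case, control,
#' other_disorder, test) and `cohort_label`. Any further columns are treated
#' as covariates and preserved untouched.
#'
#' @param x Data frame to validate.
#' @param beta Optional beta matrix; when given, every `sample_id` must be a
#'   column of it.
#' @return `x`, invisibly.
#' @export
validate_sample_sheet <- function(x, beta = NULL) {
  need <- c("sample_id", "role", "cohort_label")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample ids: ",
         x$sample_id[duplicated(x$sample_id)][1L])
  bad <- setdiff(unique(x$role), SAMPLE_ROLES)
  if (length(bad))
    stop("unknown role '", bad[1L], "'; allowed roles: ",
         paste(SAMPLE_ROLES, collapse = ", "))
  if (!is.null(beta)) {
    absent <- setdiff(x$sample_id, colnames(beta))
    if (length(absent))
      stop("sample sheet entries absent from beta matrix: ",
           paste(absent, collapse = ", "))
  }
  invisible(x)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `role`, `cohort_label` plus
#'   optional covariates.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$sample_id <- as.character(df$sample_id)
  validate_sample_sheet(df)
  df
}

#' Write a sample sheet
#' @param x Sample sheet data frame.
#' @param path Output TSV.
#' @export
write_sample_sheet <- function(x, path) {
  validate_sample_sheet(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a probe manifest
#'
#' Coordinates are 0-based; intervals are half-open `[start, end)` (BED
#' convention). A probe's `pos` is the C of the interrogated CpG.
#'
#' @param probes Data frame `probe_id`, `chrom`, `pos`.
#' @param islands Data frame `chrom`, `start`, `end` of CpG islands.
#' @param genes Data frame `gene_id`, `chrom`, `strand` (`+`/`-`), `tss`,
#'   and BED-style comma-joined `cds_starts`, `cds_ends` blocks.
#' @return Object of class `probe_manifest`.
#' @export
probe_manifest <- function(probes, islands, genes) {
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe ids in manifest")
  if (any(islands$start >= islands$end))
    stop("island intervals must satisfy start < end (half-open)")
  if (!all(genes$strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-'")
  structure(list(probes = probes, islands = islands, genes = genes),
            class = "probe_manifest")
}

#' @export
print.probe_manifest <- function(x, ...) {
  cat(sprintf("probe_manifest: %d probes on %d chromosome(s), %d islands, %d genes\n",
              nrow(x$probes), length(unique(x$probes$chrom)),
              nrow(x$islands), nrow(x$genes)))
  invisible(x)
}

#' Read a probe manifest from its three files
#'
#' @param dir Directory containing `probes.tsv`, `islands.bed`, `genes.tsv`
#'   (names overridable via the other arguments).
#' @param probes_file,islands_file,genes_file File names within `dir`.
#' @return `probe_manifest` object.
#' @export
read_probe_manifest <- function(dir, probes_file = "probes.tsv",
                                islands_file = "islands.bed",
                                genes_file = "genes.tsv") {
  probes <- utils::read.table(file.path(dir, probes_file), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  islands <- utils::read.table(file.path(dir, islands_file), header = FALSE,
                               sep = "\t", stringsAsFactors = FALSE,
                               col.names = c("chrom", "start", "end"))
  genes <- utils::read.table(file.path(dir, genes_file), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c(cds_starts = "character",
                                            cds_ends = "character"))
  probe_manifest(probes, islands, genes)
}

#' Write a probe manifest to a directory
#' @param manifest `probe_manifest` object.
#' @param dir Output directory (created if needed).
#' @export
write_probe_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(manifest$probes, file.path(dir, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest$islands, file.path(dir, "islands.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(manifest$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Validate a phenotype table
#'
#' Wide per-individual table: `individual_id`, `series` (`this_series` or
#' `literature`), then one column per clinical feature with values
#' `present`, `absent` or `unknown`.
#'
#' @param x Data frame to validate.
#' @return `x`, invisibly.
#' @export
validate_phenotype_table <- function(x) {
  need <- c("individual_id", "series")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("phenotype table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$individual_id))
    stop("duplicate individual ids: ",
         x$individual_id[duplicated(x$individual_id)][1L])
  if (!all(x$series %in% c("this_series", "literature")))
    stop("series must be 'this_series' or 'literature'")
  for (f in setdiff(names(x), need)) {
    bad <- setdiff(unique(x[[f]]), PHENO_STATES)
    if (length(bad))
      stop("feature '", f, "' has invalid state '", bad[1L],
           "'; allowed: ", paste(PHENO_STATES, collapse = ", "))
  }
  invisible(x)
}

#' Read a phenotype table
#' @param path TSV file.
#' @return Validated data frame.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_phenotype_table(df)
  df
}

#' Write a result table as TSV
#'
#' Data frames (DMP tables, DMR lists, MVP tables, prevalence rows) are
#' written as TSV in their documented column order; an empty table yields a
#' header-only file. An `episig_model` is dispatched to [write_model()].
#'
#' @param x Result object.
#' @param path Output file.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "episig_model")) return(write_model(x, path))
  if (!is.data.frame(x)) stop("write_results handles data frames and episig_model objects")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path TSV file.
#' @return Data frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
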