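#' Global methylation profile of a cohort's significant DMPs
#'
#' Restricts to probes significant at FDR < 0.05 and reports the mean
#' beta-scale methylation difference and the fraction of probes shifted
#' upward.
#'
#' @param dmp_table [moderated_t_test()] output.
#' @param q_max Significance cut (default 0.05).
#' @return List `n_significant`, `mean_methylation_difference`,
#'   `hyper_fraction` (`NA` when no probe is significant, with mean 0).
#' @export
global_profile <- function(dmp_table, q_max = 0.05) {
  sig <- dmp_table[dmp_table$q_value < q_max, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(n_significant = 0L, mean_methylation_difference = 0,
                hyper_fraction = NA_real_))
  list(n_significant = nrow(sig),
       mean_methylation_difference = mean(sig$delta_beta),
       hyper_fraction = mean(sig$delta_beta > 0))
}

#' Build a cohort profile for cross-cohort comparison
#'
#' The "top" DMP set holds the `min(number of probes significant at
#' FDR < 0.05, max_top)` probes ranked by q-value then absolute moderated
#' t (ties by probe id).
#'
#' @param dmp_table [moderated_t_test()] output.
#' @param label Cohort label.
#' @param max_top Top-set cap (default 500).
#' @return Object of class `cohort_profile`.
#' @export
cohort_profile <- function(dmp_table, label, max_top = 500L) {
  sig <- dmp_table[dmp_table$q_value < 0.05, , drop = FALSE]
  o <- order(sig$q_value, -abs(sig$moderated_t), sig$probe_id)
  top <- sig$probe_id[o][seq_len(min(nrow(sig), max_top))]
  gp <- global_profile(dmp_table)
  structure(list(cohort_label = label, dmp_table = dmp_table,
                 top_dmp_ids = top,
                 mean_methylation_difference = gp$mean_methylation_difference,
                 hyper_fraction = gp$hyper_fraction),
            class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("cohort_profile '%s': %d top DMPs, mean delta %.3f, hyper fraction %s\n",
              x$cohort_label, length(x$top_dmp_ids),
              x$mean_methylation_difference,
              format(x$hyper_fraction, digits = 3)))
  invisible(x)
}

#' Asymmetric top-DMP overlap matrix across cohorts
#'
#' Entry `(y, x)` is the percentage of the y-cohort's top probes also
#' present among the x-cohort's top probes:
#' `100 * |top(y) intersect top(x)| / |top(y)|`; the diagonal is 100. A
#' cohort with an empty top set yields a row of zeros (diagonal `NA`) and
#' a warning.
#'
#' @param profiles List of [cohort_profile()] objects (>= 2).
#' @return Numeric matrix with cohort labels on both axes.
#' @export
overlap_matrix <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 cohort profiles")
  labs <- vapply(profiles, `[[`, "", "cohort_label")
  tops <- lapply(profiles, `[[`, "top_dmp_ids")
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (y in seq_len(n)) {
    if (length(tops[[y]]) == 0L) {
      warning("cohort '", labs[y], "' has an empty top DMP set")
      m[y, ] <- 0
      m[y, y] <- NA_real_
      next
    }
    for (x in seq_len(n)) {
      m[y, x] <- 100 * length(intersect(tops[[y]], tops[[x]])) /
        length(tops[[y]])
    }
  }
  m
}

#' Euclidean tree of cohorts over median-aggregated methylation
#'
#' Aggregates each cohort to the per-probe median beta over its samples on
#' the union of all cohorts' top DMP sets, then clusters the cohort median
#' vectors agglomeratively. Node annotations carry each cohort's top-set
#' size and global mean methylation difference.
#'
#' @param beta_by_cohort Named list of beta matrices, one per cohort.
#' @param profiles List of [cohort_profile()] objects aligned with
#'   `beta_by_cohort` names.
#' @param linkage Linkage method (default `"ward.D2"`).
#' @return List with `dendrogram` (class `episig_dendrogram`), `nodes`
#'   (data frame `cohort_label`, `n_top_dmps`,
#'   `mean_methylation_difference`) and `probe_ids` used.
#' @export
cohort_tree <- function(beta_by_cohort, profiles, linkage = "ward.D2") {
  labs <- vapply(profiles, `[[`, "", "cohort_label")
  stopifnot(setequal(names(beta_by_cohort), labs))
  probe_union <- sort(unique(unlist(lapply(profiles, `[[`, "top_dmp_ids"))))
  if (length(probe_union) == 0L) stop("no top DMPs in any cohort")
  med <- vapply(labs, function(lab) {
    b <- beta_by_cohort[[lab]]
    miss <- setdiff(probe_union, rownames(b))
    if (length(miss)) stop("cohort '", lab, "' is missing probe(s): ",
                           paste(miss[1:min(3, length(miss))], collapse = ", "))
    apply(b[probe_union, , drop = FALSE], 1L, stats::median)
  }, numeric(length(probe_union)))
  m <- t(med)                       # cohorts x probes, median profiles
  colnames(m) <- probe_union
  rownames(m) <- labs
  dend <- hierarchical_cluster(t(m), probe_union, linkage = linkage)
  nodes <- data.frame(
    cohort_label = labs,
    n_top_dmps = vapply(profiles, function(p) length(p$top_dmp_ids), 0L),
    mean_methylation_difference =
      vapply(profiles, `[[`, 0, "mean_methylation_difference"),
    stringsAsFactors = FALSE)
  list(dendrogram = dend, nodes = nodes, probe_ids = probe_union)
}
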