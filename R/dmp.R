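#' Logit2 (M-value) transform of methylation betas
#'
#' `M = log2(b / (1 - b))` with betas clipped to
#' `[epsilon, 1 - epsilon]` so boundary values stay finite. Statistics are
#' computed on M-values; effect sizes are reported on the beta scale.
#'
#' @param beta Beta matrix (or vector) of methylation fractions.
#' @param epsilon Clip bound in (0, 0.5); default `1e-6`.
#' @return Object of the same shape on the M scale.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

# Newton inversion of the trigamma function (scalar y > 0); used by the
# moment-matching estimate of the prior degrees of freedom.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Empirical-Bayes squeeze of per-probe residual variances s2 with common
# residual df: moment-matching of log-variances gives the prior (d0, s0^2)
# in closed form via the inverse trigamma.
.squeeze_var <- function(s2, df) {
  n <- length(s2)
  if (n < 2L) return(list(d0 = Inf, s0_2 = mean(s2), post = s2))
  e <- log(pmax(s2, 1e-300)) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    # no excess dispersion in the log-variances: infinite prior df, and the
    # common variance is the arithmetic mean (equal variances are then a
    # fixed point: the moderated t reduces to the classic t)
    d0 <- Inf
    s0_2 <- mean(s2)
    post <- rep(s0_2, n)
  }
  list(d0 = d0, s0_2 = s0_2, post = post)
}

#' Moderated t-test for differential methylation
#'
#' Per-probe linear model on M-values with a case/control group term and
#' optional additive covariates. Residual variances are shrunk toward an
#' empirical-Bayes prior estimated by moment-matching of log-variances
#' (inverse-trigamma closed form); the moderated t uses the posterior
#' variance and `d0 + df` degrees of freedom. Effect sizes
#' (`delta_beta`) are reported on the beta scale as mean(case) -
#' mean(control); q-values are Benjamini-Hochberg across all tested probes.
#' Probes with any missing beta among the analysed samples are dropped.
#'
#' @param beta Beta matrix.
#' @param sample_sheet Sample sheet; only `case` and `control` roles enter
#'   the fit.
#' @param covariates Character vector of sheet column names used as
#'   additive adjustment terms.
#' @param epsilon Logit clip bound passed to [beta_to_m()].
#' @return A `dmp_table` data frame: `probe_id`, `mean_beta_case`,
#'   `mean_beta_control`, `delta_beta`, `moderated_t`, `p_value`,
#'   `q_value`, `direction`.
#' @export
moderated_t_test <- function(beta, sample_sheet, covariates = NULL,
                             epsilon = 1e-6) {
  validate_beta_matrix(beta)
  validate_sample_sheet(sample_sheet, beta)
  sheet <- sample_sheet[sample_sheet$role %in% c("case", "control"), ,
                        drop = FALSE]
  if (sum(sheet$role == "case") < 2L || sum(sheet$role == "control") < 2L)
    stop("need at least 2 samples per group")
  miss <- setdiff(covariates, names(sheet))
  if (length(miss)) stop("covariates absent from sample sheet: ",
                         paste(miss, collapse = ", "))

  b <- beta[, sheet$sample_id, drop = FALSE]
  keep <- !apply(is.na(b), 1L, any)
  b <- b[keep, , drop = FALSE]
  m <- beta_to_m(b, epsilon)

  grp <- as.integer(sheet$role == "case")
  dat <- data.frame(.group = grp)
  for (cv in covariates) dat[[cv]] <- sheet[[cv]]
  X <- stats::model.matrix(~ ., data = dat)
  n <- nrow(X); p <- ncol(X); df <- n - p
  if (df < 1L) stop("no residual degrees of freedom")

  fit <- stats::lm.fit(X, t(m))
  coefs <- fit$coefficients
  gi <- which(colnames(X) == ".group")
  delta_m <- coefs[gi, ]
  res <- fit$residuals
  s2 <- colSums(res^2) / df
  se_unscaled <- sqrt(chol2inv(chol(crossprod(X)))[gi, gi])

  sq <- .squeeze_var(s2, df)
  tmod <- delta_m / (sqrt(sq$post) * se_unscaled)
  # total df capped at the pooled residual df across probes
  df_total <- min(sq$d0 + df, length(s2) * df)
  pval <- 2 * stats::pt(-abs(tmod), df = df_total)

  case_ids <- sheet$sample_id[sheet$role == "case"]
  ctrl_ids <- sheet$sample_id[sheet$role == "control"]
  mean_case <- rowMeans(b[, case_ids, drop = FALSE])
  mean_ctrl <- rowMeans(b[, ctrl_ids, drop = FALSE])
  delta_beta <- mean_case - mean_ctrl

  out <- data.frame(
    probe_id = rownames(b),
    mean_beta_case = mean_case,
    mean_beta_control = mean_ctrl,
    delta_beta = delta_beta,
    moderated_t = unname(tmod),
    p_value = unname(pval),
    q_value = bh_adjust(unname(pval)),
    direction = ifelse(delta_beta > 0, "hyper", "hypo"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- list(d0 = sq$d0, s0_2 = sq$s0_2, residual_df = df)
  class(out) <- c("dmp_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; monotone in rank, capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]; `NA`/`NaN` is an
#'   error naming the offending position.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  bad <- which(is.na(p_values))
  if (length(bad)) {
    nm <- names(p_values)[bad[1L]]
    stop("NA/NaN p-value at ",
         if (is.null(nm) || nm == "") paste("position", bad[1L]) else nm)
  }
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select episignature probes from a DMP table
#'
#' Keeps probes with `q_value <= q_max` and `|delta_beta| >= delta_min`,
#' ranks by `|moderated_t|` descending (ties broken lexicographically by
#' probe id), and truncates at `max_probes`. Row order of the input table
#' is immaterial.
#'
#' @param dmp_table Output of [moderated_t_test()].
#' @param q_max FDR threshold (default 0.01).
#' @param delta_min Minimum absolute beta-scale effect (default 0.05).
#' @param max_probes Cap on signature size (default 1000).
#' @return An `episig_probes` data frame (`probe_id`, `delta_beta`,
#'   `q_value`, `moderated_t`) with the selection parameters attached;
#'   empty selection yields a zero-row set with a warning.
#' @export
select_probes <- function(dmp_table, q_max = 0.01, delta_min = 0.05,
                          max_probes = 1000L) {
  stopifnot(q_max >= 0, q_max <= 1, delta_min >= 0, max_probes >= 1)
  keep <- dmp_table$q_value <= q_max & abs(dmp_table$delta_beta) >= delta_min
  sel <- dmp_table[keep, , drop = FALSE]
  o <- order(-abs(sel$moderated_t), sel$probe_id)
  sel <- sel[o, , drop = FALSE]
  if (nrow(sel) > max_probes) sel <- sel[seq_len(max_probes), , drop = FALSE]
  if (nrow(sel) == 0L)
    warning("no probes passed selection (q_max = ", q_max,
            ", delta_min = ", delta_min, ")")
  out <- sel[, c("probe_id", "delta_beta", "q_value", "moderated_t")]
  rownames(out) <- NULL
  attr(out, "selection_params") <- list(q_max = q_max, delta_min = delta_min,
                                        max_probes = as.integer(max_probes))
  class(out) <- c("episig_probes", "data.frame")
  out
}
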