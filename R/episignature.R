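#' Partition controls and other-disorder samples for classifier training
#'
#' Cases always train; controls and each other-disorder cohort are split
#' `fraction / (1 - fraction)` train/test, stratified by `cohort_label`.
#' Samples with role `test` belong to neither partition (they are screened
#' later). A cohort with fewer than 2 samples goes wholly to train, with a
#' warning. Deterministic under `seed`.
#'
#' @param sample_sheet Sample sheet data frame.
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return List with `train_ids` and `test_ids` character vectors.
#' @export
partition_training <- function(sample_sheet, fraction = 0.75, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  validate_sample_sheet(sample_sheet)
  set.seed(.sub_seed(seed, 5L))
  train <- sample_sheet$sample_id[sample_sheet$role == "case"]
  test <- character(0)
  pool <- sample_sheet[sample_sheet$role %in% c("control", "other_disorder"), ,
                       drop = FALSE]
  for (lab in unique(pool$cohort_label)) {
    ids <- sort(pool$sample_id[pool$cohort_label == lab])
    if (length(ids) < 2L) {
      warning("cohort '", lab, "' has < 2 samples; assigned wholly to train")
      train <- c(train, ids)
      next
    }
    n_tr <- round(fraction * length(ids))
    tr <- sample(ids, n_tr)
    train <- c(train, tr)
    test <- c(test, setdiff(ids, tr))
  }
  list(train_ids = train, test_ids = test)
}

.probe_ids_of <- function(probe_set) {
  if (is.character(probe_set)) probe_set else probe_set$probe_id
}

#' Train the episignature classifier
#'
#' Binary linear-kernel SVM (case versus controls + other disorders) on the
#' beta values of the signature probes, with Platt sigmoid calibration of
#' the decision values into Methylation Variant Pathogenicity (MVP) scores.
#' The squared-hinge primal is solved deterministically, so retraining on
#' identical inputs reproduces the weights.
#'
#' @param beta Beta matrix.
#' @param probe_set [select_probes()] output or a character vector of probe
#'   ids; must be non-empty.
#' @param train_ids Training sample ids (see [partition_training()]).
#' @param sample_sheet Sample sheet covering `train_ids`.
#' @param cost Soft-margin cost parameter (default 1).
#' @param input_scale `"beta"` (default, matching the clustering substrate)
#'   or `"m"` to classify on M-values.
#' @return Object of class `episig_model`.
#' @export
train_classifier <- function(beta, probe_set, train_ids, sample_sheet,
                             cost = 1, input_scale = c("beta", "m")) {
  input_scale <- match.arg(input_scale)
  probes <- .probe_ids_of(probe_set)
  if (length(probes) == 0L) stop("probe set is empty")
  missing_p <- setdiff(probes, rownames(beta))
  if (length(missing_p))
    stop("probes absent from beta matrix: ", paste(missing_p, collapse = ", "))
  missing_s <- setdiff(train_ids, colnames(beta))
  if (length(missing_s))
    stop("training samples absent from beta matrix: ",
         paste(missing_s, collapse = ", "))
  roles <- sample_sheet$role[match(train_ids, sample_sheet$sample_id)]
  y <- ifelse(roles == "case", 1, -1)
  if (length(unique(y)) < 2L)
    stop("training set must contain cases and non-cases")

  X <- t(beta[probes, train_ids, drop = FALSE])
  if (input_scale == "m") X <- beta_to_m(X)
  svm <- .svm_fit(X, y, cost)
  f <- drop(X %*% svm$weights) + svm$intercept
  cal <- .platt_fit(f, y)

  structure(list(
    schema_version = MODEL_SCHEMA_VERSION,
    probe_ids = probes,
    weights = svm$weights,
    intercept = svm$intercept,
    calibration = cal,
    cost = cost,
    input_scale = input_scale,
    train_ids = train_ids[y == 1],
    train_negative_ids = train_ids[y == -1]),
    class = "episig_model")
}

#' @export
print.episig_model <- function(x, ...) {
  cat(sprintf(paste0(
    "episignature classifier (linear SVM, Platt-calibrated)\n",
    "  probes: %d   training: %d cases vs %d non-cases   cost: %g   input: %s\n"),
    length(x$probe_ids), length(x$train_ids), length(x$train_negative_ids),
    x$cost, x$input_scale))
  invisible(x)
}

#' @export
coef.episig_model <- function(object, ...) {
  stats::setNames(c(object$weights, object$intercept),
                  c(object$probe_ids, "(intercept)"))
}

#' Score samples with a trained episignature model
#'
#' Produces one calibrated MVP score in \[0, 1\] per sample. Every
#' signature probe must be present in the matrix; missing probes are an
#' error, never silently imputed.
#'
#' @param model `episig_model`.
#' @param beta Beta matrix.
#' @param sample_ids Samples to score (default: all columns).
#' @return Data frame `sample_id`, `mvp_score`, `partition`
#'   (`train`/`test` relative to the model's own training split).
#' @export
mvp_score <- function(model, beta, sample_ids = colnames(beta)) {
  stopifnot(inherits(model, "episig_model"))
  missing_p <- setdiff(model$probe_ids, rownames(beta))
  if (length(missing_p))
    stop("probes absent from beta matrix: ", paste(missing_p, collapse = ", "))
  missing_s <- setdiff(sample_ids, colnames(beta))
  if (length(missing_s))
    stop("samples absent from beta matrix: ",
         paste(missing_s, collapse = ", "))
  X <- t(beta[model$probe_ids, sample_ids, drop = FALSE])
  if (model$input_scale == "m") X <- beta_to_m(X)
  f <- drop(X %*% model$weights) + model$intercept
  trained_on <- c(model$train_ids, model$train_negative_ids)
  data.frame(
    sample_id = sample_ids,
    mvp_score = unname(.platt_prob(f, model$calibration$A,
                                   model$calibration$B)),
    partition = ifelse(sample_ids %in% trained_on, "train", "test"),
    stringsAsFactors = FALSE)
}

#' @export
predict.episig_model <- function(object, beta,
                                 sample_ids = colnames(beta), ...) {
  mvp_score(object, beta, sample_ids)
}

#' Leave-one-out cross-validation of the episignature
#'
#' For each case in turn: drop it, re-run probe selection and classifier
#' training on the remaining samples, score the held-out case, and record
#' whether it joins the case branch when the selected-probe dendrogram is
#' cut in two. The number of rounds equals the number of cases.
#'
#' @param beta Beta matrix.
#' @param sample_sheet Sample sheet (needs >= 3 cases).
#' @param q_max,delta_min,max_probes Selection parameters, as in
#'   [select_probes()].
#' @param fraction,seed Training-partition parameters.
#' @param cost SVM cost.
#' @return Data frame with one row per round: `round`, `held_out`,
#'   `n_probes`, `mvp_score`, `clusters_with_cases`.
#' @export
loo_cross_validate <- function(beta, sample_sheet, q_max = 0.01,
                               delta_min = 0.05, max_probes = 1000L,
                               fraction = 0.75, seed = 1L, cost = 1) {
  case_ids <- sample_sheet$sample_id[sample_sheet$role == "case"]
  if (length(case_ids) < 3L) stop("leave-one-out needs at least 3 cases")
  rounds <- lapply(seq_along(case_ids), function(i) {
    held <- case_ids[i]
    sheet_i <- sample_sheet[sample_sheet$sample_id != held, , drop = FALSE]
    dmp <- moderated_t_test(beta, sheet_i)
    sel <- select_probes(dmp, q_max, delta_min, max_probes)
    part <- partition_training(sheet_i, fraction, seed)
    model <- train_classifier(beta, sel, part$train_ids, sheet_i, cost)
    score <- mvp_score(model, beta, held)$mvp_score

    clusters_with_cases <- NA
    if (nrow(sel) >= 1L) {
      keep <- c(setdiff(case_ids, held),
                sheet_i$sample_id[sheet_i$role == "control"], held)
      dend <- hierarchical_cluster(beta[, keep, drop = FALSE], sel)
      k2 <- stats::cutree(dend$hclust, k = 2L)
      case_branch <- as.integer(names(which.max(
        table(k2[setdiff(case_ids, held)]))))
      clusters_with_cases <- unname(k2[held]) == case_branch
    }
    data.frame(round = i, held_out = held, n_probes = nrow(sel),
               mvp_score = score, clusters_with_cases = clusters_with_cases,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rounds)
}

#' Screen samples against a trained episignature
#'
#' Scores the given samples and returns them in descending MVP order with
#' a call flag at the given threshold.
#'
#' @param model `episig_model`.
#' @param beta Beta matrix.
#' @param screen_ids Sample ids to screen (empty gives an empty table).
#' @param threshold Call threshold on the MVP score (default 0.5).
#' @return Data frame `sample_id`, `mvp_score`, `partition` (`"screen"`),
#'   `flagged`.
#' @export
screen_samples <- function(model, beta, screen_ids, threshold = 0.5) {
  if (length(screen_ids) == 0L)
    return(data.frame(sample_id = character(0), mvp_score = numeric(0),
                      partition = character(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  tab <- mvp_score(model, beta, screen_ids)
  tab$partition <- "screen"
  tab$flagged <- tab$mvp_score >= threshold
  tab[order(-tab$mvp_score, tab$sample_id), , drop = FALSE]
}

#' Serialize an episignature model to versioned JSON
#' @param model `episig_model`.
#' @param path Output file.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "episig_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an episignature model written by [write_model()]
#' @param path JSON file.
#' @return `episig_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) ||
      obj$schema_version != MODEL_SCHEMA_VERSION)
    stop("unsupported or missing model schema_version in ", path)
  need <- c("probe_ids", "weights", "intercept", "calibration")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("model file missing fields: ",
                         paste(miss, collapse = ", "))
  structure(obj, class = "episig_model")
}
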