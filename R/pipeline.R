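#' Assemble and validate a discovery-pipeline configuration
#'
#' Either point at existing inputs (`beta_path`, `sheet_path`,
#' `manifest_dir`) or enable simulation (`simulate = TRUE`), in which case
#' the fixture-suite cohort is generated under `seed` before analysis.
#' All stage parameters are validated here, before any computation.
#'
#' @param out_dir Output directory for all result files.
#' @param beta_path,sheet_path,manifest_dir Input file locations (ignored
#'   when `simulate = TRUE`).
#' @param simulate Generate the synthetic fixture cohort instead of
#'   reading inputs.
#' @param n_probes Probe count for simulation.
#' @param q_max,delta_min,max_probes Probe-selection parameters.
#' @param train_fraction Training split fraction.
#' @param maxgap,min_probes,probe_q_max DMR-caller parameters.
#' @param mvp_threshold Screening call threshold.
#' @param run_loocv Run leave-one-out cross-validation (default TRUE).
#' @param seed Global seed; every stochastic stage derives its stream from
#'   it.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(out_dir, beta_path = NULL, sheet_path = NULL,
                       manifest_dir = NULL, simulate = is.null(beta_path),
                       n_probes = 10000L, q_max = 0.01, delta_min = 0.05,
                       max_probes = 1000L, train_fraction = 0.75,
                       maxgap = 1000L, min_probes = 3L, probe_q_max = 0.05,
                       mvp_threshold = 0.5, run_loocv = TRUE, seed = 1L) {
  if (!(q_max >= 0 && q_max <= 1)) stop("q_max must lie in [0, 1]")
  if (!(probe_q_max > 0 && probe_q_max <= 1))
    stop("probe_q_max must lie in (0, 1]")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie in (0, 1)")
  if (delta_min < 0) stop("delta_min must be non-negative")
  if (max_probes < 1 || min_probes < 1 || maxgap < 1)
    stop("max_probes, min_probes and maxgap must be positive")
  if (!(mvp_threshold >= 0 && mvp_threshold <= 1))
    stop("mvp_threshold must lie in [0, 1]")
  if (!simulate && (is.null(beta_path) || is.null(sheet_path) ||
                    is.null(manifest_dir)))
    stop("either enable simulate or provide beta_path, sheet_path and manifest_dir")
  structure(as.list(environment()), class = "run_config")
}

#' Run the discovery pipeline end to end
#'
#' Differential methylation, probe selection, unsupervised structure
#' (dendrogram + MDS), classifier training with held-out test partition,
#' optional leave-one-out cross-validation, screening of all `test`-role
#' samples, DMR calling, and context annotation. Writes every stage's
#' result table plus a machine-readable run manifest (inputs, parameters,
#' seed, package version) to `out_dir`; identical configurations produce
#' identical result files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_discovery_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (config$simulate) {
    cfg <- fixture_config(seed = config$seed, n_probes = config$n_probes)
    manifest <- stage("simulate", simulate_manifest(cfg))
    sim <- stage("simulate", simulate_cohort(cfg, manifest))
    beta <- sim$beta; sheet <- sim$sheet
    write_results(sim$truth$signature,
                  file.path(config$out_dir, "truth_signature.tsv"))
  } else {
    beta <- stage("read", read_beta_matrix(config$beta_path))
    sheet <- stage("read", read_sample_sheet(config$sheet_path))
    manifest <- stage("read", read_probe_manifest(config$manifest_dir))
  }

  dmp <- stage("dmp", moderated_t_test(beta, sheet))
  write_results(as.data.frame(dmp), file.path(config$out_dir, "dmp.tsv"))

  sel <- stage("select", select_probes(dmp, config$q_max, config$delta_min,
                                       config$max_probes))
  write_results(as.data.frame(sel), file.path(config$out_dir, "probes.tsv"))

  disc_ids <- sheet$sample_id[sheet$role %in% c("case", "control")]
  dend <- stage("cluster",
                hierarchical_cluster(beta[, disc_ids, drop = FALSE], sel))
  embed <- stage("cluster", mds_embed(beta, sel))
  write_results(embed, file.path(config$out_dir, "mds.tsv"))

  part <- stage("train", partition_training(sheet, config$train_fraction,
                                            config$seed))
  model <- stage("train", train_classifier(beta, sel, part$train_ids, sheet))
  write_model(model, file.path(config$out_dir, "model.json"))
  scores <- stage("score",
                  mvp_score(model, beta, c(part$train_ids, part$test_ids)))
  write_results(scores, file.path(config$out_dir, "mvp_train_test.tsv"))

  loocv <- NULL
  if (config$run_loocv) {
    loocv <- stage("loocv",
                   loo_cross_validate(beta, sheet, config$q_max,
                                      config$delta_min, config$max_probes,
                                      config$train_fraction, config$seed))
    write_results(loocv, file.path(config$out_dir, "loocv.tsv"))
  }

  screen_ids <- sheet$sample_id[sheet$role == "test"]
  screen <- stage("screen", screen_samples(model, beta, screen_ids,
                                           config$mvp_threshold))
  write_results(screen, file.path(config$out_dir, "mvp_screen.tsv"))

  dmrs <- stage("dmr", call_dmrs(dmp, manifest, config$maxgap,
                                 config$min_probes, config$probe_q_max))
  write_results(dmrs, file.path(config$out_dir, "dmrs.tsv"))

  annot <- stage("annotate", annotate_probes(sel$probe_id, manifest))
  write_results(annot, file.path(config$out_dir, "probe_context.tsv"))
  if (nrow(sel) > 0L)
    write_results(summarize_context(annot),
                  file.path(config$out_dir, "context_summary.tsv"))

  manifest_json <- list(
    package = "episignr",
    version = as.character(utils::packageVersion("episignr")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "out_dir")],
    outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest_json,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  invisible(list(beta = beta, sheet = sheet, manifest = manifest,
                 dmp = dmp, probes = sel, dendrogram = dend,
                 embedding = embed, partition = part, model = model,
                 scores = scores, loocv = loocv, screen = screen,
                 dmrs = dmrs, annotations = annot))
}

#' Screen a beta matrix against a serialized model
#'
#' Reads a model JSON and a beta matrix, scores the requested samples and
#' writes an MVP table with call flags and a provenance header.
#'
#' @param model_path Model JSON from [write_model()].
#' @param beta_path Beta matrix TSV.
#' @param out_path Output TSV.
#' @param screen_ids Samples to score (default: all columns).
#' @param threshold Call threshold (default 0.5).
#' @return The screening table, invisibly.
#' @export
run_screen <- function(model_path, beta_path, out_path,
                       screen_ids = NULL, threshold = 0.5) {
  model <- read_model(model_path)
  beta <- read_beta_matrix(beta_path)
  if (is.null(screen_ids)) screen_ids <- colnames(beta)
  tab <- screen_samples(model, beta, screen_ids, threshold)
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# episignr %s screen: model=%s beta=%s threshold=%g",
                     as.character(utils::packageVersion("episignr")),
                     model_path, beta_path, threshold), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
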