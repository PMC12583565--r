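test_that("training partition is stratified, complete and deterministic", {
  fx <- fixture_suite()
  p1 <- partition_training(fx$sheet, 0.75, seed = 7)
  p2 <- partition_training(fx$sheet, 0.75, seed = 7)
  expect_identical(p1, p2)
  expect_length(intersect(p1$train_ids, p1$test_ids), 0)

  sheet <- fx$sheet
  # all cases train; controls split 30/10; each 12-sample cohort 9/3
  expect_true(all(sheet$sample_id[sheet$role == "case"] %in% p1$train_ids))
  ctrl <- sheet$sample_id[sheet$role == "control"]
  expect_equal(sum(ctrl %in% p1$train_ids), 30L)
  expect_equal(sum(ctrl %in% p1$test_ids), 10L)
  for (lab in c("disorderA", "disorderB", "disorderC")) {
    ids <- sheet$sample_id[sheet$cohort_label == lab]
    expect_equal(sum(ids %in% p1$train_ids), 9L)
    expect_equal(sum(ids %in% p1$test_ids), 3L)
  }
  # test-role samples belong to neither partition
  expect_length(intersect(sheet$sample_id[sheet$role == "test"],
                          c(p1$train_ids, p1$test_ids)), 0)

  tiny <- rbind(sheet,
                data.frame(sample_id = "solo_01", role = "other_disorder",
                           cohort_label = "solo"))
  expect_warning(p3 <- partition_training(tiny, 0.75, seed = 7),
                 "wholly to train")
  expect_true("solo_01" %in% p3$train_ids)
})

test_that("classifier training is deterministic and separates the fixture", {
  fx <- fixture_suite()
  fm <- fixture_model()
  m2 <- train_classifier(fx$beta, fixture_probes(), fm$part$train_ids,
                         fx$sheet)
  expect_equal(fm$model$weights, m2$weights, tolerance = 1e-8)
  expect_equal(fm$model$intercept, m2$intercept, tolerance = 1e-8)

  sc <- mvp_score(fm$model, fx$beta, fm$part$train_ids)
  roles <- fx$sheet$role[match(sc$sample_id, fx$sheet$sample_id)]
  expect_true(all(sc$mvp_score[roles == "case"] > 0.9))
  expect_true(all(sc$mvp_score[roles != "case"] < 0.1))
  expect_true(all(sc$partition == "train"))

  ctrl_only <- fx$sheet[fx$sheet$role == "control", ]
  expect_error(train_classifier(fx$beta, fixture_probes(),
                                ctrl_only$sample_id, fx$sheet),
               "cases and non-cases")
  expect_error(train_classifier(fx$beta, character(0),
                                fm$part$train_ids, fx$sheet), "empty")
})

test_that("scoring stays in [0,1] and refuses missing probes", {
  fx <- fixture_suite()
  fm <- fixture_model()
  sc <- mvp_score(fm$model, fx$beta)
  expect_true(all(sc$mvp_score >= 0 & sc$mvp_score <= 1))
  shrunk <- fx$beta[-match(fm$model$probe_ids[1], rownames(fx$beta)), ]
  expect_error(mvp_score(fm$model, shrunk),
               fm$model$probe_ids[1], fixed = TRUE)
  expect_equal(predict(fm$model, fx$beta, "ctrl_01"),
               mvp_score(fm$model, fx$beta, "ctrl_01"))
})

test_that("MVP is monotone in the mosaic dilution fraction", {
  cfg <- sim_config(n_probes = 4000L, n_cases = 14L, n_controls = 30L,
                    n_signature_probes = 200L, mean_delta = 0.15,
                    hyper_fraction = 0.9, precision = 50,
                    mosaic_fractions = rep(c(0, 0.25, 0.5, 0.75, 1), 3),
                    seed = 19L)
  man <- simulate_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  dmp <- moderated_t_test(sim$beta, sim$sheet)
  sel <- select_probes(dmp)
  part <- partition_training(sim$sheet, 0.75, seed = 19L)
  model <- train_classifier(sim$beta, sel, part$train_ids, sim$sheet)
  tr <- sim$truth$samples
  mos <- tr[grepl("^mosaic", tr$sample_id), ]
  sc <- mvp_score(model, sim$beta, mos$sample_id)
  med <- tapply(sc$mvp_score, mos$mosaic_fraction[
    match(sc$sample_id, mos$sample_id)], median)
  expect_true(!is.unsorted(med))
  # f = 0.5 scores strictly between the control and case medians
  ctrl_med <- median(mvp_score(model, sim$beta,
    sim$sheet$sample_id[sim$sheet$role == "control"])$mvp_score)
  case_med <- median(mvp_score(model, sim$beta,
    sim$sheet$sample_id[sim$sheet$role == "case"])$mvp_score)
  f5 <- sc$mvp_score[mos$mosaic_fraction[
    match(sc$sample_id, mos$sample_id)] == 0.5]
  expect_true(all(f5 > ctrl_med & f5 < case_med))
})

test_that("screening ranks, flags and handles empty input", {
  fx <- fixture_suite()
  fm <- fixture_model()
  screen_ids <- fx$sheet$sample_id[fx$sheet$role == "test"]
  tab <- screen_samples(fm$model, fx$beta, screen_ids)
  expect_true(!is.unsorted(rev(tab$mvp_score)))
  expect_true(all(tab$partition == "screen"))
  expect_identical(tab$flagged, tab$mvp_score >= 0.5)

  # training cases themselves are flagged (sanity)
  case_tab <- screen_samples(fm$model, fx$beta,
                             fx$sheet$sample_id[fx$sheet$role == "case"])
  expect_true(all(case_tab$flagged))

  empty <- screen_samples(fm$model, fx$beta, character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("leave-one-out reruns selection per round and guards small n", {
  fx <- toy_groups(n_probes = 300, n_case = 4, n_ctrl = 8, delta = 0.35,
                   n_sig = 30, seed = 55)
  loo <- loo_cross_validate(fx$beta, fx$sheet, seed = 55)
  expect_equal(nrow(loo), 4L)
  expect_equal(loo$held_out, fx$sheet$sample_id[fx$sheet$role == "case"])
  expect_true(all(loo$n_probes > 0))

  two <- fx$sheet[!fx$sheet$sample_id %in% c("case_1", "case_2"), ]
  expect_error(loo_cross_validate(fx$beta, two), "at least 3 cases")
})
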