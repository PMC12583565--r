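test_that("beta_to_m is the clipped logit2 transform", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0, epsilon = 1e-6), log2(1e-6 / (1 - 1e-6)))
  b <- matrix(c(0.25, 0.75), 1, 2,
              dimnames = list("cg1", c("a", "b")))
  expect_equal(beta_to_m(b), matrix(c(log2(1/3), log2(3)), 1, 2,
                                    dimnames = dimnames(b)))
})

test_that("moderated t matches a from-scratch oracle to 1e-10", {
  set.seed(21)
  n_probes <- 50; n <- 8
  ids <- c(paste0("case_", 1:4), paste0("ctrl_", 1:4))
  beta <- matrix(runif(n_probes * n, 0.2, 0.8), n_probes, n,
                 dimnames = list(sprintf("cg%03d", 1:n_probes), ids))
  beta[1:5, 1:4] <- pmin(beta[1:5, 1:4] + 0.25, 0.95)
  sheet <- data.frame(sample_id = ids,
                      role = rep(c("case", "control"), each = 4),
                      cohort_label = "x", stringsAsFactors = FALSE)
  got <- moderated_t_test(beta, sheet)
  oracle <- modt_oracle(beta_to_m(beta), rep(c(1, 0), each = 4))
  expect_equal(got$moderated_t, unname(oracle$t), tolerance = 1e-10)
  expect_equal(got$p_value, unname(oracle$p), tolerance = 1e-10)
  expect_equal(got$delta_beta,
               unname(rowMeans(beta[, 1:4]) - rowMeans(beta[, 5:8])),
               tolerance = 1e-12)
  expect_equal(got$direction, ifelse(got$delta_beta > 0, "hyper", "hypo"))
  expect_true(all(got$q_value >= got$p_value - 1e-15))
})

test_that("equal per-probe variances reduce the moderated t to the classic t", {
  # same residuals for every probe: the prior collapses onto the common
  # variance, so moderation is a fixed point of the ordinary t
  set.seed(4)
  n <- 10
  e <- rnorm(n)
  grp <- rep(c(1, 0), each = n / 2)
  mvals <- t(sapply(1:20, function(i) 0.3 * i + (0.1 * i) * grp + e))
  beta <- 2^mvals / (1 + 2^mvals)
  dimnames(beta) <- list(sprintf("cg%02d", 1:20),
                         c(paste0("case_", 1:5), paste0("ctrl_", 1:5)))
  sheet <- data.frame(sample_id = colnames(beta),
                      role = rep(c("case", "control"), each = 5),
                      cohort_label = "x", stringsAsFactors = FALSE)
  got <- moderated_t_test(beta, sheet, epsilon = 1e-12)
  m <- beta_to_m(beta, 1e-12)
  classic <- apply(m, 1, function(y) {
    fit <- lm(y ~ grp)
    summary(fit)$coefficients["grp", "t value"]
  })
  expect_equal(got$moderated_t, unname(classic), tolerance = 1e-6)
  prior <- attr(got, "prior")
  expect_identical(prior$d0, Inf)
})

test_that("moderated t agrees with the limma implementation", {
  library(limma)
  fx <- toy_groups(n_probes = 200, n_case = 5, n_ctrl = 5, seed = 31)
  got <- moderated_t_test(fx$beta, fx$sheet)
  m <- beta_to_m(fx$beta)
  design <- cbind(1, fx$sheet$role == "case")
  efit <- eBayes(lmFit(m, design))
  expect_equal(attr(got, "prior")$d0, efit$df.prior, tolerance = 1e-6)
  expect_equal(attr(got, "prior")$s0_2, efit$s2.prior, tolerance = 1e-6)
  expect_equal(got$moderated_t, unname(efit$t[, 2]), tolerance = 1e-8)
  expect_equal(got$p_value, unname(efit$p.value[, 2]), tolerance = 1e-8)
})

test_that("covariate adjustment and group-size guards work", {
  fx <- toy_groups(n_probes = 40, n_case = 5, n_ctrl = 5, seed = 13)
  fx$sheet$age <- c(5, 9, 12, 7, 10, 6, 11, 8, 9, 10)
  got <- moderated_t_test(fx$beta, fx$sheet, covariates = "age")
  expect_equal(nrow(got), 40L)
  expect_error(moderated_t_test(fx$beta, fx$sheet, covariates = "batch"),
               "absent from sample sheet")
  small <- fx$sheet
  small$role[small$role == "case"] <- c("case", rep("test", 4))
  expect_error(moderated_t_test(fx$beta, small), "at least 2 samples")
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.05 * 4 / 3, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(a = 0.1, b = NA)), "\\bb\\b")
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:500) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("probe selection applies thresholds, ranking and the cap", {
  dmp <- fixture_dmp()
  sel <- fixture_probes()
  expect_true(all(sel$q_value <= 0.01))
  expect_true(all(abs(sel$delta_beta) >= 0.05))
  expect_true(!is.unsorted(rev(abs(sel$moderated_t))))

  # invariant to input row order
  shuf <- dmp[sample(nrow(dmp)), ]
  expect_equal(as.data.frame(select_probes(shuf)), as.data.frame(sel))

  capped <- select_probes(dmp, max_probes = 10)
  expect_equal(nrow(capped), 10L)
  expect_equal(capped$probe_id, sel$probe_id[1:10])

  null_dmp <- dmp
  null_dmp$q_value <- 1
  expect_warning(empty <- select_probes(null_dmp), "no probes passed")
  expect_equal(nrow(empty), 0L)
})

test_that("probe recovery on the planted fixture is sensitive and precise", {
  fx <- fixture_suite()
  sel <- fixture_probes()
  truth <- fx$truth$signature$probe_id
  expect_gte(mean(truth %in% sel$probe_id), 0.8)   # sensitivity
  expect_gte(mean(sel$probe_id %in% truth), 0.8)   # precision
})
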