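test_that("a hand-checkable 6-probe run yields exactly one hyper DMR", {
  pos <- 100000L + 150L * (0:5)
  probes <- data.frame(probe_id = sprintf("cg%02d", 1:6),
                       chrom = "chr1", pos = pos)
  dmp <- do.call(rbind, lapply(1:6, function(i)
    dmp_row(probes$probe_id[i], delta = 0.2, p = 1e-8, q = 1e-6)))
  dmrs <- call_dmrs(dmp, tiny_manifest(probes))
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$n_probes, 6L)
  expect_equal(dmrs$start, pos[1])
  expect_equal(dmrs$end, pos[6] + 1L)
  # Stouffer of six identical one-sided z-scores: z * sqrt(6)
  z1 <- qnorm(1e-8 / 2, lower.tail = FALSE)
  expect_equal(dmrs$combined_z, z1 * sqrt(6), tolerance = 1e-9)
  expect_equal(dmrs$region_p, pnorm(z1 * sqrt(6), lower.tail = FALSE))
  expect_equal(dmrs$region_q, dmrs$region_p)  # single candidate
})

test_that("min_probes, direction and gap rules split or drop runs", {
  probes <- data.frame(probe_id = sprintf("cg%02d", 1:7), chrom = "chr1",
                       pos = c(1000L, 1200L, 1400L, 5000L,
                               20000L, 20100L, 20200L))
  man <- tiny_manifest(probes)

  # isolated significant probe: below min_probes, no region
  iso <- rbind(dmp_row("cg04", 0.2, 1e-8, 1e-6),
               dmp_row("cg01", 0.01, 0.9, 0.95))
  expect_equal(nrow(call_dmrs(iso, man)), 0L)

  # adjacent significant probes with opposite signs never merge
  mixed <- do.call(rbind, lapply(1:3, function(i)
    dmp_row(sprintf("cg%02d", i), delta = c(0.2, -0.2, 0.2)[i],
            p = 1e-8, q = 1e-6)))
  expect_equal(nrow(call_dmrs(mixed, man)), 0L)

  # two clean clusters with opposite directions: one region each
  two <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      dmp_row(sprintf("cg%02d", i), 0.2, 1e-8, 1e-6))),
    do.call(rbind, lapply(5:7, function(i)
      dmp_row(sprintf("cg%02d", i), -0.2, 1e-8, 1e-6))))
  dmrs <- call_dmrs(two, man)
  expect_equal(nrow(dmrs), 2L)
  expect_equal(summarize_dmr_directions(dmrs),
               c(n_total = 2L, n_hyper = 1L, n_hypo = 1L))
  # row order of the input table is immaterial
  dmrs2 <- call_dmrs(two[sample(nrow(two)), ], man)
  expect_equal(dmrs2, dmrs)

  expect_error(call_dmrs(dmp_row("missing", 0.2, 1e-8), man), "missing")
  expect_equal(summarize_dmr_directions(call_dmrs(iso, man)),
               c(n_total = 0L, n_hyper = 0L, n_hypo = 0L))
})

test_that("12 planted hyper clusters are recovered as 12 hyper DMRs", {
  # manifest with 12 tight probe clusters (6 probes, 150 bp apart) plus
  # scattered background probes
  n_bg <- 428L
  set.seed(61)
  cl_start <- seq(1e5, 12e5, length.out = 12)
  cl_pos <- as.integer(rep(cl_start, each = 6) + 150L * (0:5))
  bg_pos <- sort(sample((2e6):(8e6), n_bg))
  probes <- data.frame(
    probe_id = sprintf("cg%04d", seq_len(72L + n_bg)),
    chrom = "chr1",
    pos = c(cl_pos, bg_pos))
  man <- tiny_manifest(probes)
  cfg <- sim_config(n_probes = 500L, n_cases = 14L, n_controls = 30L,
                    n_signature_probes = 72L, mean_delta = 0.2,
                    hyper_fraction = 1, precision = 50, seed = 61L)
  sim <- simulate_cohort(cfg, man,
                         signature_probe_ids = probes$probe_id[1:72])
  dmp <- moderated_t_test(sim$beta, sim$sheet)
  dmrs <- call_dmrs(dmp, man)
  counts <- summarize_dmr_directions(dmrs)
  expect_equal(unname(counts["n_total"]), 12L)
  expect_equal(unname(counts["n_hypo"]), 0L)

  # interval recovery: every planted cluster matches a called region with
  # Jaccard overlap >= 0.8
  planted <- data.frame(start = as.integer(cl_start),
                        end = as.integer(cl_start + 150 * 5 + 1))
  jacc <- vapply(seq_len(12), function(i) {
    ov <- pmax(0, pmin(dmrs$end, planted$end[i]) -
                 pmax(dmrs$start, planted$start[i]))
    un <- pmax(dmrs$end, planted$end[i]) - pmin(dmrs$start, planted$start[i])
    max(ov / un)
  }, numeric(1))
  expect_true(all(jacc >= 0.8))

  # every emitted region satisfies its structural invariants
  expect_true(all(dmrs$end > dmrs$start))
  expect_true(all(dmrs$n_probes >= 3L))
  for (r in seq_len(nrow(dmrs))) {
    ids <- strsplit(dmrs$probe_ids[r], ",")[[1]]
    p <- man$probes[match(ids, man$probes$probe_id), ]
    expect_true(all(diff(p$pos) <= 1000))
    expect_equal(length(unique(dmp$direction[match(ids, dmp$probe_id)])), 1L)
  }
})
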