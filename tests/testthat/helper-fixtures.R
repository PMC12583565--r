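# Shared fixtures, memoized so expensive simulations run once per suite.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# full fixture suite: 14 discovery cases, 40 controls, 3 other-disorder
# cohorts, validation/unresolved/VUS/mosaic test samples (seed fixed)
fixture_suite <- function() {
  memo("suite", {
    cfg <- fixture_config(seed = 42L, n_probes = 10000L)
    manifest <- simulate_manifest(cfg)
    sim <- simulate_cohort(cfg, manifest)
    list(cfg = cfg, manifest = manifest, beta = sim$beta,
         sheet = sim$sheet, truth = sim$truth)
  })
}

fixture_dmp <- function() {
  fx <- fixture_suite()
  memo("suite_dmp", moderated_t_test(fx$beta, fx$sheet))
}

fixture_probes <- function() memo("suite_probes", select_probes(fixture_dmp()))

fixture_model <- function() {
  fx <- fixture_suite()
  memo("suite_model", {
    part <- partition_training(fx$sheet, 0.75, seed = 42L)
    model <- train_classifier(fx$beta, fixture_probes(), part$train_ids,
                              fx$sheet)
    list(part = part, model = model)
  })
}

# small beta matrix with known groups for fast unit tests
toy_groups <- function(n_probes = 60, n_case = 4, n_ctrl = 4, delta = 0.3,
                       n_sig = 10, seed = 11) {
  set.seed(seed)
  mu <- runif(n_probes, 0.2, 0.8)
  ids <- c(sprintf("case_%d", seq_len(n_case)),
           sprintf("ctrl_%d", seq_len(n_ctrl)))
  beta <- sapply(seq_along(ids), function(j) {
    m <- mu
    if (j <= n_case) m[seq_len(n_sig)] <- pmin(m[seq_len(n_sig)] + delta, 0.95)
    pmin(pmax(rbeta(n_probes, m * 80, (1 - m) * 80), 0.001), 0.999)
  })
  dimnames(beta) <- list(sprintf("cg%05d", seq_len(n_probes)), ids)
  sheet <- data.frame(
    sample_id = ids,
    role = rep(c("case", "control"), c(n_case, n_ctrl)),
    cohort_label = rep(c("case", "control"), c(n_case, n_ctrl)),
    stringsAsFactors = FALSE)
  list(beta = beta, sheet = sheet, sig = rownames(beta)[seq_len(n_sig)])
}

# ---- independent oracles -------------------------------------------------

# Benjamini-Hochberg step-up, written as the textbook algorithm
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# moderated t computed probe by probe from the definition: per-probe lm(),
# log-variance moment matching with a uniroot-based trigamma inversion
modt_oracle <- function(m, group) {
  n <- length(group)
  fits <- apply(m, 1, function(y) {
    fit <- lm(y ~ group)
    s2 <- sum(residuals(fit)^2) / fit$df.residual
    c(coef(fit)[["group"]], s2, fit$df.residual)
  })
  delta <- fits[1, ]; s2 <- fits[2, ]; df <- fits[3, 1]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * uniroot(function(x) trigamma(x) - evar, c(1e-6, 1e8),
                      tol = 1e-12)$root
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    post <- rep(mean(s2), length(s2))
  }
  se <- sqrt(1 / sum(group == 1) + 1 / sum(group == 0))
  tmod <- delta / (sqrt(post) * se)
  df_total <- min(d0 + df, length(s2) * df)
  list(t = tmod, p = 2 * pt(-abs(tmod), df = df_total), d0 = d0)
}

# CpG context by linear scan over every island, no indexing
cpg_oracle <- function(chrom, pos, islands) {
  vapply(seq_along(pos), function(i) {
    isl <- islands[islands$chrom == chrom[i], , drop = FALSE]
    if (nrow(isl) == 0) return("inter_CGI")
    inside <- any(pos[i] >= isl$start & pos[i] < isl$end)
    if (inside) return("island")
    d <- min(pmax(isl$start - pos[i] - 1, 0) + pmax(pos[i] - isl$end, 0))
    if (d <= 2000) "shore" else if (d <= 4000) "shelf" else "inter_CGI"
  }, character(1))
}

# gene context by linear scan over every gene and CDS block
gene_oracle <- function(chrom, pos, genes) {
  vapply(seq_along(pos), function(i) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return("intergenic")
    u <- ifelse(g$strand == "+", g$tss - pos[i], pos[i] - g$tss)
    if (any(u >= 1 & u <= 1000)) return("promoter")
    if (any(u > 1000 & u <= 5000)) return("promoter_plus")
    for (j in seq_len(nrow(g))) {
      st <- as.integer(strsplit(g$cds_starts[j], ",")[[1]])
      en <- as.integer(strsplit(g$cds_ends[j], ",")[[1]])
      if (any(pos[i] >= st & pos[i] < en)) return("CDS")
    }
    "intergenic"
  }, character(1))
}

# hand-buildable DMP table for DMR-caller tests
dmp_row <- function(probe_id, delta, p, q = p) {
  data.frame(probe_id = probe_id, mean_beta_case = 0.5 + delta,
             mean_beta_control = 0.5, delta_beta = delta,
             moderated_t = sign(delta) * 5, p_value = p, q_value = q,
             direction = ifelse(delta > 0, "hyper", "hypo"),
             stringsAsFactors = FALSE)
}

tiny_manifest <- function(probes) {
  probe_manifest(
    probes,
    islands = data.frame(chrom = "chr1", start = 10000L, end = 11000L),
    genes = data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                       tss = 50000L, cds_starts = "50000",
                       cds_ends = "52000", stringsAsFactors = FALSE))
}
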