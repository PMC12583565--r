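test_that("CpG categories follow the island-distance definitions", {
  islands <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  expect_equal(annotate_cpg_context("chr1", 10500L, islands), "island")
  expect_equal(annotate_cpg_context("chr1", 12500L, islands), "shore")
  expect_equal(annotate_cpg_context("chr1", 14500L, islands), "shelf")
  expect_equal(annotate_cpg_context("chr1", 20000L, islands), "inter_CGI")
  # island boundaries: first base inside vs first base outside
  expect_equal(annotate_cpg_context("chr1", 10000L, islands), "island")
  expect_equal(annotate_cpg_context("chr1", 11000L, islands), "shore")
  # other chromosome: islands do not project across chromosomes
  expect_equal(annotate_cpg_context("chr2", 10500L, islands), "inter_CGI")
})

test_that("gene categories are strand-aware with promoter precedence", {
  genes <- data.frame(
    gene_id = c("fwd", "rev"), chrom = "chr1", strand = c("+", "-"),
    tss = c(50000L, 90000L),
    cds_starts = c("50000", "88000"), cds_ends = c("52000", "90000"),
    stringsAsFactors = FALSE)
  got <- annotate_gene_context(rep("chr1", 5),
                               c(49500L, 47000L, 90500L, 51000L, 70000L),
                               genes)
  expect_equal(got$gene_category,
               c("promoter", "promoter_plus", "promoter", "CDS",
                 "intergenic"))
  expect_equal(got$nearest_gene_id[1:4], c("fwd", "fwd", "rev", "fwd"))

  # promoter of one gene beats CDS of another (category precedence)
  overlapping <- rbind(genes,
                       data.frame(gene_id = "host", chrom = "chr1",
                                  strand = "+", tss = 40000L,
                                  cds_starts = "40000", cds_ends = "49900"))
  got2 <- annotate_gene_context("chr1", 49500L, overlapping)
  expect_equal(got2$gene_category, "promoter")
  expect_equal(got2$nearest_gene_id, "fwd")

  bad <- genes; bad$strand[1] <- "."
  expect_error(annotate_gene_context("chr1", 49500L, bad), "strand")
})

test_that("annotation agrees with a linear-scan oracle on random probes", {
  cfg <- sim_config(n_probes = 1000L, seed = 71L)
  man <- simulate_manifest(cfg)
  ann <- annotate_probes(man$probes$probe_id, man)
  expect_equal(ann$cpg_category,
               cpg_oracle(man$probes$chrom, man$probes$pos, man$islands))
  expect_equal(ann$gene_category,
               gene_oracle(man$probes$chrom, man$probes$pos, man$genes))
  # categories exhaustive and exclusive by construction
  expect_true(all(ann$cpg_category %in%
                    c("island", "shore", "shelf", "inter_CGI")))
  expect_true(all(ann$gene_category %in%
                    c("promoter", "promoter_plus", "CDS", "intergenic")))
  expect_error(annotate_probes("not_a_probe", man), "not_a_probe")
})

test_that("DMRs are annotated by midpoint", {
  probes <- data.frame(probe_id = c("cg01", "cg02", "cg03"), chrom = "chr1",
                       pos = c(10100L, 10300L, 10500L))
  man <- tiny_manifest(probes)  # island at [10000, 11000)
  dmp <- do.call(rbind, lapply(1:3, function(i)
    dmp_row(probes$probe_id[i], 0.2, 1e-8, 1e-6)))
  dmrs <- call_dmrs(dmp, man)
  ann <- annotate_dmrs(dmrs, man)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$cpg_category, "island")
  expect_equal(ann$feature_id, "chr1:10100-10501")
  expect_equal(nrow(annotate_dmrs(dmrs[0, ], man)), 0L)
})

test_that("context summaries give integer percents that sum to 100", {
  ann <- data.frame(
    feature_id = sprintf("f%02d", 1:20),
    cpg_category = rep(c("shore", "inter_CGI", "island", "shelf"),
                       c(9, 7, 3, 1)),
    gene_category = rep("promoter", 20),
    stringsAsFactors = FALSE)
  s <- summarize_context(ann)
  cpg <- s[s$axis == "cpg", ]
  expect_equal(cpg$percent[match(c("shore", "inter_CGI", "island", "shelf"),
                                 cpg$category)], c(45, 35, 15, 5))
  gene <- s[s$axis == "gene", ]
  expect_equal(gene$percent[gene$category == "promoter"], 100)
  expect_equal(sum(gene$percent), 100)

  # property: percents sum to exactly 100 for random category draws
  set.seed(81)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    a <- data.frame(
      feature_id = seq_len(n),
      cpg_category = sample(c("island", "shore", "shelf", "inter_CGI"), n,
                            replace = TRUE),
      gene_category = sample(c("promoter", "promoter_plus", "CDS",
                               "intergenic"), n, replace = TRUE))
    s <- summarize_context(a)
    expect_equal(sum(s$percent[s$axis == "cpg"]), 100)
    expect_equal(sum(s$percent[s$axis == "gene"]), 100)
  }
  expect_error(summarize_context(ann[0, ]), "no annotations")
})
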