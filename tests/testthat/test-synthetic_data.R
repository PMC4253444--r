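test_that("manifest simulation is deterministic and respects annotation geometry", {
  d <- sim_design(n_probes = 3000, n_genes = 60, n_chromosomes = 2)
  sm1 <- simulate_manifest(d, seed = 101)
  sm2 <- simulate_manifest(d, seed = 101)
  expect_identical(sm1, sm2)
  sm3 <- simulate_manifest(d, seed = 102)
  expect_false(identical(sm1$manifest$pos, sm3$manifest$pos))

  m <- sm1$manifest; genes <- sm1$genes; islands <- sm1$islands
  expect_equal(nrow(m), 3000L)
  expect_true(all(table(m$chr) > 0))
  for (cc in unique(m$chr)) expect_true(all(diff(m$pos[m$chr == cc]) > 0))
  expect_true(all(m$feature %in% genic_features()))
  expect_true(all(m$island %in% island_relations()))

  ## genic features agree with an independent recomputation from gene models
  for (i in sample(nrow(m), 300)) {
    gg <- genes[genes$chr == m$chr[i], ]
    d_up <- ifelse(gg$strand == "+", gg$tss - m$pos[i], m$pos[i] - gg$tss)
    in200 <- any(d_up > 0 & d_up <= 200)
    if (in200) expect_equal(m$feature[i], "TSS200")
    lo <- pmin(gg$tss, gg$tts); hi <- pmax(gg$tss, gg$tts)
    if (!any(m$pos[i] >= lo - 1500 & m$pos[i] <= hi + 1500)) {
      expect_equal(m$feature[i], "Intergenic")
    }
  }

  ## island relation agrees with distance to the nearest island edge
  for (i in sample(nrow(m), 300)) {
    isl <- islands[islands$chr == m$chr[i], ]
    inside <- any(m$pos[i] >= isl$start & m$pos[i] <= isl$end)
    dist <- min(pmax(isl$start - m$pos[i], m$pos[i] - isl$end))
    if (inside) {
      expect_equal(m$island[i], "Island")
    } else if (dist <= 2000) {
      expect_match(m$island[i], "Shore")
    } else if (dist <= 4000) {
      expect_match(m$island[i], "Shelf")
    } else {
      expect_equal(m$island[i], "OpenSea")
    }
  }
})

test_that("a null cohort has no planted truth and near-zero empirical deltas", {
  d <- sim_design(n_probes = 2000, n_genes = 50,
                  group_sizes = c(normal = 20, HCC_EtOH = 20),
                  effects = list(), dmr_spec = NULL, precision = 50)
  sm <- simulate_manifest(d, seed = 31)
  co <- simulate_cohort(sm, d, seed = 32)
  expect_equal(nrow(co$truth$effects), 0L)
  expect_equal(nrow(co$truth$dmrs), 0L)
  g <- split(co$sheet$sample_id, co$sheet$group)
  emp <- rowMeans(co$beta[, g$HCC_EtOH]) - rowMeans(co$beta[, g$normal])
  expect_gte(mean(abs(emp) < 0.05), 0.99)
})

test_that("planted effects are recovered in the group means and same seed reproduces", {
  d <- sim_design(n_probes = 2000, n_genes = 50,
                  group_sizes = c(normal = 20, HCC_EtOH = 20),
                  effects = list(sim_effect("e", tissues = "HCC",
                                            etiologies = "EtOH", n = 100,
                                            delta = 0.3, frac_hyper = 1)),
                  dmr_spec = NULL, t12_frac = 1, precision = 50)
  sm <- simulate_manifest(d, seed = 41)
  co <- simulate_cohort(sm, d, seed = 42)
  co2 <- simulate_cohort(sm, d, seed = 42)
  expect_identical(co$beta, co2$beta)

  g <- split(co$sheet$sample_id, co$sheet$group)
  emp <- rowMeans(co$beta[, g$HCC_EtOH]) - rowMeans(co$beta[, g$normal])
  planted <- co$truth$effects$probe_id
  expect_length(planted, 100L)
  expect_true(all(abs(emp[planted] - 0.3) < 0.05))
  expect_true(all(co$beta >= 0 & co$beta <= 1))
})

test_that("stage scaling shapes cirrhosis and late-stage effect magnitudes", {
  d <- sim_design(n_probes = 2000, n_genes = 50,
                  group_sizes = c(normal = 20, cirrhosis_HCV = 20, HCC_HCV = 20),
                  effects = list(sim_effect("e", tissues = c("cirrhosis", "HCC"),
                                            etiologies = "HCV", n = 120,
                                            delta = 0.3, frac_hyper = 1)),
                  dmr_spec = NULL, t12_frac = 0, precision = 200)
  sm <- simulate_manifest(d, seed = 51)
  co <- simulate_cohort(sm, d, seed = 52)
  g <- split(co$sheet$sample_id, co$sheet$group)
  planted <- co$truth$effects$probe_id
  d_cirr <- rowMeans(co$beta[planted, g$cirrhosis_HCV]) -
    rowMeans(co$beta[planted, g$normal])
  d_hcc <- rowMeans(co$beta[planted, g$HCC_HCV]) -
    rowMeans(co$beta[planted, g$normal])
  expect_equal(mean(d_cirr), 0.5 * 0.3, tolerance = 0.05)
  expect_equal(mean(d_hcc), 1.3 * 0.3, tolerance = 0.05)  # all T3+T4 here
})

test_that("expression simulation honours sample count, coupling and the null", {
  d <- sim_design(n_probes = 2000, n_genes = 200,
                  group_sizes = c(normal = 10), effects = list(),
                  dmr_spec = NULL,
                  expression_coupling = list(enabled = TRUE,
                                             promoter_margin = 0.3,
                                             body_margin = 0.15,
                                             n_samples = 7, probes_per_gene = 3))
  sm <- simulate_manifest(d, seed = 61)
  expect_true(all(c("high", "mid", "low") %in% sm$genes$expr_class))

  ex <- simulate_expression(sm$genes, n_samples = 7, seed = 62)
  expect_equal(ncol(ex$intensities), 7L)
  expect_equal(nrow(ex$intensities), 3L * nrow(sm$genes))
  expect_identical(ex, simulate_expression(sm$genes, n_samples = 7, seed = 62))

  ## coupled: designated high genes express above designated low genes
  es <- summarize_expression(ex$intensities, ex$probe_gene)
  mu <- setNames(es$mean_intensity, es$gene)
  expect_gt(mean(mu[ex$strata$high]), mean(mu[ex$strata$low]) + 5)

  ## coupling off everywhere: expression unrelated to promoter methylation
  d0 <- sim_design(n_probes = 2000, n_genes = 200,
                   group_sizes = c(normal = 10), effects = list(),
                   dmr_spec = NULL)
  sm0 <- simulate_manifest(d0, seed = 61)
  co0 <- simulate_cohort(sm0, d0, seed = 63)
  ex0 <- simulate_expression(sm0$genes, n_samples = 7, coupled = FALSE, seed = 64)
  es0 <- summarize_expression(ex0$intensities, ex0$probe_gene)
  tssp <- c("TSS200", "TSS1500", "5UTR", "1stExon")
  promoter_beta <- vapply(es0$gene, function(g) {
    pr <- sm0$manifest$probe_id[!is.na(sm0$manifest$gene) &
                                  sm0$manifest$gene == g &
                                  sm0$manifest$feature %in% tssp]
    if (!length(pr)) return(NA_real_)
    mean(co0$beta[pr, ])
  }, numeric(1))
  ok <- !is.na(promoter_beta)
  expect_gt(sum(ok), 150)
  expect_lt(abs(cor(es0$mean_intensity[ok], promoter_beta[ok])), 0.2)
})

test_that("clone-table simulation is exact at the extremes and binomial in between", {
  expect_true(all(simulate_clone_table(5, 8, 0, seed = 1) == 0))
  expect_true(all(simulate_clone_table(5, 8, 1, seed = 1) == 1))
  expect_error(simulate_clone_table(5, 8, 1.5), "\\[0, 1\\]")
  tab <- simulate_clone_table(50, 10, 0.3, seed = 2)
  expect_equal(dim(tab), c(50L, 10L))
  ## 99.9% binomial bound around p = 0.3 with 500 Bernoulli draws
  ci <- qbinom(c(5e-4, 1 - 5e-4), 500, 0.3) / 500
  expect_gte(mean(tab), ci[1])
  expect_lte(mean(tab), ci[2])
})
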