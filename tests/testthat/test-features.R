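test_that("feature distribution counts calls per category and normalizes", {
  m <- toy_manifest(6)
  m$island <- c("Island", "Island", "OpenSea", "OpenSea", "N_Shore", "OpenSea")
  m$feature <- c("TSS200", "TSS200", "Body", "Body", "Body", "Intergenic")
  m$gene <- c("G1", "G1", "G2", "G2", "G3", NA)

  calls <- structure(list(comparison = "x", hyper = m$probe_id[1:2],
                          hypo = m$probe_id[3:6]), class = "cpg_calls")
  fd <- feature_distribution(calls, m)

  isl_hyper <- fd[fd$direction == "hyper" & fd$vocabulary == "island", ]
  expect_equal(isl_hyper$proportion[isl_hyper$category == "Island"], 1)
  expect_equal(sum(isl_hyper$proportion), 1)

  isl_hypo <- fd[fd$direction == "hypo" & fd$vocabulary == "island", ]
  expect_equal(isl_hypo$proportion[isl_hypo$category == "OpenSea"], 0.75)
  expect_equal(isl_hypo$proportion[isl_hypo$category == "N_Shore"], 0.25)
  gen_hypo <- fd[fd$direction == "hypo" & fd$vocabulary == "genic", ]
  expect_equal(gen_hypo$proportion[gen_hypo$category == "Body"], 0.75)
  expect_equal(gen_hypo$proportion[gen_hypo$category == "Intergenic"], 0.25)

  ## every non-empty direction normalizes to 1 over each vocabulary
  agg <- aggregate(proportion ~ direction + vocabulary, fd, sum)
  expect_true(all(abs(agg$proportion - 1) < 1e-9))

  empty <- structure(list(comparison = "x", hyper = character(),
                          hypo = m$probe_id[1]), class = "cpg_calls")
  fd2 <- feature_distribution(empty, m)
  expect_true(all(is.na(fd2$proportion[fd2$direction == "hyper"])))

  bad <- structure(list(comparison = "x", hyper = "nope", hypo = character()),
                   class = "cpg_calls")
  expect_error(feature_distribution(bad, m), "absent from manifest")
})

test_that("per-gene feature means aggregate member probes", {
  m <- toy_manifest(5)
  m$gene <- c("G1", "G2", "G2", NA, "G3")
  m$feature <- c("TSS200", "TSS200", "TSS200", "Intergenic", "Body")
  d <- toy_diff(m$probe_id, c(0.2, 0.1, 0.3, 0.9, -0.4))
  tab <- per_gene_feature_delta(d, m)
  expect_equal(tab$TSS200[tab$gene == "G1"], 0.2)
  expect_equal(tab$TSS200[tab$gene == "G2"], 0.2)  # mean(0.1, 0.3)
  expect_equal(tab$Body[tab$gene == "G3"], -0.4)
  expect_true(is.na(tab$Body[tab$gene == "G1"]))
  expect_false("G4" %in% tab$gene)  # absent gene stays absent
  expect_false("Intergenic" %in% names(tab))
})

test_that("feature correlation matches closed forms and recovers a planted rho", {
  tab <- data.frame(gene = c("a", "b", "c"), TSS200 = c(0, 1, 2),
                    `1stExon` = c(0, 2, 4), check.names = FALSE)
  fc <- feature_correlation(tab, "TSS200", "1stExon")
  expect_equal(fc$r, 1)
  expect_equal(fc$slope, 2)
  expect_equal(fc$intercept, 0)

  ident <- data.frame(gene = letters[1:5], x = 1:5, y = 1:5)
  fi <- feature_correlation(ident, "x", "y")
  expect_equal(fi$r, 1)
  expect_equal(fi$slope, 1)

  two <- data.frame(gene = c("a", "b", "c"), x = c(1, 2, NA), y = c(1, 2, 3))
  expect_error(feature_correlation(two, "x", "y"), "at least 3")

  ## bivariate construction with known correlation 0.8, 500 genes
  set.seed(77)
  z <- rnorm(500)
  x <- 0.2 * z
  y <- 0.2 * (0.8 * z + sqrt(1 - 0.8^2) * rnorm(500))
  tab2 <- data.frame(gene = sprintf("g%03d", 1:500), TSS200 = x,
                     `1stExon` = y, check.names = FALSE)
  fc2 <- feature_correlation(tab2, "TSS200", "1stExon")
  expect_equal(fc2$r, 0.8, tolerance = 0.1 / 0.8)
  expect_lt(fc2$p, 1e-10)
})

test_that("gene-scoped promoter effects couple TSS200 and 1st-exon differentials", {
  d <- sim_design(n_probes = 6000, n_genes = 150,
                  group_sizes = c(normal = 12, HCC_HCV = 12),
                  effects = list(sim_effect("promo", tissues = "HCC",
                                            etiologies = "HCV", n = 80,
                                            delta = c(0.1, 0.4), frac_hyper = 1,
                                            scope = "gene_promoter")),
                  dmr_spec = NULL, t12_frac = 1)
  sm <- simulate_manifest(d, seed = 71)
  co <- simulate_cohort(sm, d, seed = 72)
  g <- split(co$sheet$sample_id, co$sheet$group)
  diffT <- compare_groups(co$beta, g$normal, g$HCC_HCV)
  tab <- per_gene_feature_delta(diffT, sm$manifest)
  fc <- feature_correlation(tab, "TSS200", "1stExon")
  expect_gt(fc$r, 0.6)
  expect_gt(fc$slope, 0)
})

test_that("metagene profile is exact on constant input and bins by strand", {
  m <- toy_manifest(60, start = 1000L, step = 300L)
  genes <- data.frame(gene = "G1", chr = "chr1", strand = "+",
                      tss = 6000L, tts = 16000L)
  vals <- setNames(rep(0.5, nrow(m)), m$probe_id)
  prof <- metagene_profile(vals, m, genes)
  expect_equal(nrow(prof), 100L)
  occupied <- prof$n_probes > 0
  expect_true(any(occupied))
  expect_true(all(prof$mean_value[occupied] == 0.5))
  expect_true(all(is.na(prof$mean_value[!occupied])))
  expect_equal(sort(unique(prof$region)), c("body", "downstream", "upstream"))

  ## minus-strand orientation: probes right of the TSS are upstream
  gm <- data.frame(gene = "Gm", chr = "chr1", strand = "-",
                   tss = 10000L, tts = 4000L)
  m2 <- data.frame(probe_id = c("a", "b", "c"), chr = "chr1",
                   pos = c(10100L, 7000L, 3900L), strand = "+", gene = NA,
                   feature = "Body", island = "OpenSea")
  p2 <- metagene_profile(setNames(c(0.1, 0.5, 0.9), m2$probe_id), m2, gm)
  expect_equal(p2$region[p2$n_probes > 0 & p2$mean_value %in% 0.1], "upstream")
  expect_equal(p2$region[p2$n_probes > 0 & p2$mean_value %in% 0.5], "body")
  expect_equal(p2$region[p2$n_probes > 0 & p2$mean_value %in% 0.9], "downstream")
  ## 100 bp past the TSS lands in the last upstream bin (0-200 bp offset)
  expect_equal(p2$bin[p2$n_probes > 0][1], 25L)

  ## hand-placed probes in a 10 kb gene reproduce manual bin assignment
  gp <- data.frame(gene = "Gp", chr = "chr1", strand = "+",
                   tss = 20000L, tts = 30000L)
  mp <- data.frame(probe_id = sprintf("h%d", 1:5), chr = "chr1",
                   pos = c(15500L, 19990L, 20000L, 25100L, 34900L),
                   strand = "+", gene = NA, feature = "Body", island = "OpenSea")
  vp <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5), mp$probe_id)
  pp <- metagene_profile(vp, mp, gp)
  ## h1: 4500 bp upstream -> upstream bin ceiling(4500/200)=23 from TSS -> bin 3
  expect_equal(pp$mean_value[3], 0.1)
  ## h2: 10 bp upstream -> last upstream bin (25)
  expect_equal(pp$mean_value[25], 0.2)
  ## h3: exactly at the TSS -> first body bin (26)
  expect_equal(pp$mean_value[26], 0.3)
  ## h4: 51% of the body -> body bin floor(0.51*50)+1 = 26 -> global 51
  expect_equal(pp$mean_value[51], 0.4)
  ## h5: 4900 bp downstream -> downstream bin 25 -> global 100
  expect_equal(pp$mean_value[100], 0.5)
  expect_equal(sum(pp$n_probes), 5L)

  ## zero-length gene is skipped with a warning
  g0 <- data.frame(gene = "G0", chr = "chr1", strand = "+",
                   tss = 5000L, tts = 5000L)
  expect_warning(p0 <- metagene_profile(vp, mp, g0), "zero-length")
  expect_equal(sum(p0$n_probes), 0L)
})

test_that("probes contribute to every overlapping gene window", {
  genes <- data.frame(gene = c("A", "B"), chr = "chr1", strand = "+",
                      tss = c(10000L, 22000L), tts = c(20000L, 32000L))
  ## probe at 21000: 1000 bp downstream of A and 1000 bp upstream of B
  m <- data.frame(probe_id = "x", chr = "chr1", pos = 21000L, strand = "+",
                  gene = NA, feature = "Body", island = "OpenSea")
  prof <- metagene_profile(c(x = 0.7), m, genes)
  expect_equal(sum(prof$n_probes), 2L)
  expect_setequal(prof$region[prof$n_probes > 0], c("upstream", "downstream"))
})
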