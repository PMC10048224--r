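test_that("identical config reproduces cohorts byte for byte", {
  cfg <- small_config(seed = 11)
  a <- generate_cohort(cfg, 1L)
  b <- generate_cohort(cfg, 1L)
  expect_identical(a$expr, b$expr)
  expect_identical(a$ann, b$ann)
  s1 <- generate_study(small_config(seed = 3))
  s2 <- generate_study(small_config(seed = 3))
  expect_identical(s1$cohorts[[2]]$mirna, s2$cohorts[[2]]$mirna)
  expect_identical(igraph::as_edgelist(s1$ppi), igraph::as_edgelist(s2$ppi))
})

test_that("EMT effect is planted at the configured log2 magnitude", {
  # null effect: planted-module genes show no class difference
  cfg0 <- small_config(seed = 5, emt_effect_lfc = 0)
  co0 <- generate_cohort(cfg0, 2L)  # intensity cohort: values are log-scale
  emt <- co0$ann$subtype == "EMT"
  planted <- names(synthetic_truth(cfg0)$de_genes)
  d0 <- rowMeans(co0$expr[planted, emt]) - rowMeans(co0$expr[planted, !emt])
  expect_lt(abs(mean(d0)), 0.15)

  # configured effect 2, low noise, 100 samples per arm
  cfg2 <- synthetic_config(
    n_genes = 120L, n_mirnas = 0L, cohort_sizes = 200L,
    platforms = "intensity", emt_fraction = 0.5,
    module_plan = data.frame(size = 40L, loading_mean = 0.6, loading_sd = 0.1),
    emt_effect_lfc = 2, intensity_noise_sd = 0.1, seed = 7)
  co <- generate_cohort(cfg2, 1L)
  emt <- co$ann$subtype == "EMT"
  planted <- names(synthetic_truth(cfg2)$de_genes)
  d <- rowMeans(co$expr[planted, emt]) - rowMeans(co$expr[planted, !emt])
  expect_lt(abs(mean(d) - 2), 0.2)
})

test_that("effect calibration holds within 10% across 20 seeds", {
  diffs <- vapply(1:20, function(s) {
    cfg <- synthetic_config(
      n_genes = 80L, n_mirnas = 0L, cohort_sizes = 200L,
      platforms = "counts", emt_fraction = 0.5,
      module_plan = data.frame(size = 30L, loading_mean = 0.6,
                               loading_sd = 0.1),
      emt_effect_lfc = 2, base_range = c(5, 9), libsize_sd = 0, seed = s)
    co <- generate_cohort(cfg, 1L)
    # equal library sizes by construction: raw counts measure the effect
    # without confounding it with size-factor estimation
    q <- unclass(co$expr)[, ]
    emt <- co$ann$subtype == "EMT"
    planted <- names(synthetic_truth(cfg)$de_genes)
    # realized LFC: log2 ratio of group-mean counts
    mean(log2(rowMeans(q[planted, emt]) / rowMeans(q[planted, !emt])))
  }, numeric(1))
  expect_true(all(abs(diffs - 2) <= 0.2))
})

test_that("planted motifs are triangles of the emitted network", {
  cfg <- small_config(seed = 2)
  g <- generate_ppi(cfg)
  tri <- enumerate_triangles(g)
  expect_true(all(triple_keys(cfg$planted_motifs) %in% triple_keys(tri)))

  # zero background, one planted triple: exactly the 3 planted edges
  one <- small_config(seed = 2, ppi_background_density = 0,
                      planted_motifs = rbind(c("g0001", "g0002", "g0003")))
  g0 <- generate_ppi(one)
  expect_equal(igraph::ecount(g0), 3L)
  expect_equal(nrow(enumerate_triangles(g0)), 1L)
})

test_that("background edge count follows the Bernoulli density", {
  cfg <- synthetic_config(n_genes = 200L, n_mirnas = 0L, cohort_sizes = 10L,
                          platforms = "counts",
                          module_plan = data.frame(size = 20L,
                                                   loading_mean = 0.6,
                                                   loading_sd = 0.1),
                          ppi_background_density = 0.01,
                          planted_motifs = rbind(c("g0001", "g0002", "g0003")),
                          seed = 9)
  g <- generate_ppi(cfg)
  npairs <- choose(200, 2)
  expected <- 0.01 * npairs
  sd <- sqrt(npairs * 0.01 * 0.99)
  expect_lt(abs(igraph::ecount(g) - 3 - expected), 3 * sd + 3)
})

test_that("null survival times follow the configured exponential law", {
  passes <- vapply(1:20, function(s) {
    cfg <- synthetic_config(
      n_genes = 20L, n_mirnas = 0L, cohort_sizes = 500L,
      platforms = "intensity", module_plan = data.frame(
        size = 10L, loading_mean = 0.6, loading_sd = 0.1),
      survival_betas = stats::setNames(numeric(0), character(0)),
      age_beta = 0, sex_beta = 0, baseline_hazard = 0.05,
      censor_rate = 0, seed = s)
    co <- generate_cohort(cfg, 1L)
    ann <- generate_survival(co$expr, co$ann, cfg, 1L)
    expect_true(all(ann$event == 1L))
    suppressWarnings(stats::ks.test(ann$time, "pexp", 0.05)$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(passes), 18L)
})

test_that("heavy censoring drives the event fraction toward zero", {
  cfg <- small_config(seed = 4, baseline_hazard = 0.001, censor_rate = 1)
  co <- generate_cohort(cfg, 1L)
  ann <- generate_survival(co$expr, co$ann, cfg, 1L)
  expect_lt(mean(ann$event), 0.05)
})

test_that("miRNA layer represses its targets as configured", {
  cfg <- synthetic_config(
    n_genes = 50L, n_mirnas = 1L, cohort_sizes = 40L,
    platforms = "intensity",
    module_plan = data.frame(size = 10L, loading_mean = 0.6, loading_sd = 0.1),
    mirna_target_map = data.frame(mirna = "mir001", gene = "g0020",
                                  strength = 1),
    mirna_noise_sd = 0, discriminative_mirnas = character(0),
    discriminative_shifts = numeric(0), seed = 6)
  co <- generate_cohort(cfg, 1L)
  ml <- generate_mirna_layer(co$expr, co$ann, cfg, 1L)
  z <- as.numeric(scale(co$expr["g0020", ]))
  expect_equal(unname(ml$mirna["mir001", ]), -z, tolerance = 1e-12)
  expect_true(all(ml$targets$validated))
})

test_that("empty target map yields pure-noise miRNAs and an empty table", {
  cfg <- small_config(seed = 8)
  cfg$mirna_target_map <- NULL
  co <- generate_cohort(cfg, 1L)
  ml <- generate_mirna_layer(co$expr, co$ann, cfg, 1L)
  expect_equal(nrow(ml$targets), 0L)
  expect_lt(abs(mean(ml$mirna)), 0.1)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(module_plan = data.frame(
    size = 500L, loading_mean = 0.6, loading_sd = 0.1), n_genes = 100L),
    "exceed")
  expect_error(synthetic_config(
    planted_motifs = rbind(c("g0099", "g0100", "g0101")), n_genes = 200L,
    module_plan = data.frame(size = 40L, loading_mean = 0.6,
                             loading_sd = 0.1)),
    "EMT module")
  cfg <- small_config()
  expect_error(generate_cohort(cfg, 1L, platform = "microarray"), "platform")
  expect_error(generate_cohort(cfg, 5L), "cohort_index")
})

test_that("a study can be written to and read back from disk", {
  dir <- withr::local_tempdir()
  study <- generate_study(small_config(seed = 12))
  write_study(study, dir)
  expr <- read_expression(file.path(dir, "cohort1_expr.tsv"), "counts")
  expect_equal(unclass(expr)[, ], unclass(study$cohorts[[1]]$expr)[, ])
  ann <- read_annotations(file.path(dir, "cohort1_ann.tsv"))
  expect_equal(ann$sample_id, study$cohorts[[1]]$ann$sample_id)
  g <- read_network(file.path(dir, "ppi.sif"))
  expect_equal(igraph::ecount(g), igraph::ecount(study$ppi))
})
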