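two_class_cohort <- function(n_per = 50, shift = 0, seed = 1,
                             genes = c("gA", "gB", "gC")) {
  set.seed(seed)
  n <- 2 * n_per
  m <- matrix(rnorm(length(genes) * n), length(genes), n,
              dimnames = list(genes, sprintf("s%03d", 1:n)))
  lab <- rep(c("EMT", "other"), each = n_per)
  m[, lab == "EMT"] <- m[, lab == "EMT"] + shift
  list(expr = m, labels = lab)
}

test_that("logistic fit separates planted shifts and flags separation", {
  null <- two_class_cohort(100, shift = 0, seed = 31)
  fit0 <- logistic_fit(t(null$expr), null$labels)
  null2 <- two_class_cohort(100, shift = 0, seed = 131)
  auc0 <- roc_auc(predict(fit0, t(null2$expr)), null2$labels)$auc
  expect_lt(abs(auc0 - 0.5), 0.07)

  tr <- two_class_cohort(100, shift = 2, seed = 32)
  va <- two_class_cohort(100, shift = 2, seed = 33)
  fit <- logistic_fit(t(tr$expr), tr$labels)
  expect_gte(roc_auc(predict(fit, t(va$expr)), va$labels)$auc, 0.95)

  # perfectly separable toy: separation flagged, ridge keeps coefs finite
  xs <- matrix(c(0:4, 10:14), 10, 1, dimnames = list(NULL, "g"))
  ys <- rep(c("other", "EMT"), each = 5)
  sep <- logistic_fit(xs, ys)
  expect_true(sep$separation)
  expect_true(all(is.finite(sep$coefficients)))
  expect_error(logistic_fit(xs, rep("EMT", 10)), "class")
})

test_that("ROC AUC equals the Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("EMT", "EMT", "other", "other"))$auc, 1)
  expect_equal(roc_auc(c(3, 1, 2, 0), c("EMT", "EMT", "other", "other"))$auc,
               0.75)
  set.seed(34)
  for (i in 1:100) {
    sc <- rnorm(30)
    if (i %% 3 == 0) sc <- round(sc)       # exercise ties
    lab <- sample(c("EMT", "other"), 30, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    r <- roc_auc(sc, lab)
    flipped <- roc_auc(sc, ifelse(lab == "EMT", "other", "EMT"))$auc
    expect_equal(r$auc + flipped, 1, tolerance = 1e-12)
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    wil <- suppressWarnings(stats::wilcox.test(sc[lab == "EMT"],
                                               sc[lab == "other"]))
    expect_equal(r$auc,
                 unname(wil$statistic) / (sum(lab == "EMT") * sum(lab == "other")),
                 tolerance = 1e-12)
  }
})

test_that("frozen cross-cohort validation never refits", {
  tr <- two_class_cohort(60, shift = 1.5, seed = 35)
  fit <- logistic_fit(t(tr$expr), tr$labels)
  cohorts <- list(train = tr, copy = tr)
  r1 <- cross_cohort_validate(fit, cohorts)
  r2 <- cross_cohort_validate(fit, cohorts)
  expect_identical(r1, r2)
  expect_equal(r1$train$auc, r1$copy$auc)

  perm <- tr
  set.seed(36); perm$labels <- sample(perm$labels)
  expect_lt(abs(cross_cohort_validate(fit, list(p = perm))$p$auc - 0.5), 0.12)
  bad <- tr; rownames(bad$expr) <- c("x", "y", "z")
  expect_error(cross_cohort_validate(fit, list(b = bad)), "missing")
})

test_that("the three-cohort diagnostic protocol reaches high AUC on a planted motif", {
  cfg <- small_config(seed = 37)
  study <- generate_study(cfg)
  motif <- cfg$planted_motifs[1, ]
  co1 <- study$cohorts[[1]]; co2 <- study$cohorts[[2]]
  d <- motif_diagnostics(motif,
                         train = list(expr = co1$expr, labels = co1$ann$subtype),
                         validation = list(expr = co2$expr,
                                           labels = co2$ann$subtype),
                         independent = list(expr = co2$expr,
                                            labels = co2$ann$subtype))
  expect_gte(d$roc$train$auc, 0.9)
  expect_gte(d$roc$validation$auc, 0.9)
  expect_gte(d$roc$independent$auc, 0.9)
})

test_that("tumor/normal split validation is stratified and reproducible", {
  co <- two_class_cohort(40, shift = 2, seed = 38)
  lab <- ifelse(co$labels == "EMT", "tumor", "normal")
  set.seed(39)
  r1 <- tumor_normal_validate(rownames(co$expr), co$expr, lab, split = 0.7)
  set.seed(39)
  r2 <- tumor_normal_validate(rownames(co$expr), co$expr, lab, split = 0.7)
  expect_identical(r1$train_ids, r2$train_ids)
  expect_gte(r1$roc_test$auc, 0.9)
  expect_equal(sum(lab[colnames(co$expr) %in% r1$train_ids] == "tumor"),
               round(0.7 * 40))
})

test_that("miRNA candidacy needs both differential expression and a motif target", {
  de <- data.frame(feature_id = c("m1", "m2", "m3"),
                   padj = c(0.01, 0.5, 0.001))
  targets <- data.frame(mirna = c("m1", "m2", "m4"),
                        gene = c("gA", "gA", "gB"), validated = TRUE)
  expect_equal(candidate_mirnas(de, targets, c("gA", "gB")), "m1")
  expect_length(candidate_mirnas(de, targets, "gZ"), 0L)
  targets2 <- rbind(targets, data.frame(mirna = "m3", gene = "gB",
                                        validated = FALSE))
  expect_false("m3" %in% candidate_mirnas(de, targets2, c("gA", "gB")))
})

test_that("LDA emits a linear index with the expected geometry", {
  set.seed(40)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("EMT", "other"), 50)
  fit0 <- lda_fit(x, y)
  expect_lt(abs(fit0$training_auc - 0.5), 0.12)

  # 1-D two-Gaussian: coefficient sign follows the mean ordering
  x1 <- matrix(c(rnorm(60, 1), rnorm(60, -1)), ncol = 1,
               dimnames = list(NULL, "f"))
  y1 <- rep(c("EMT", "other"), each = 60)
  fit1 <- lda_fit(x1, y1)
  expect_gt(fit1$coefficients[["f"]], 0)

  # collinear duplicate feature takes the ridge path, coefficients finite
  xc <- cbind(f1 = x1[, 1], f2 = x1[, 1])
  fitc <- lda_fit(xc, y1)
  expect_true(fitc$ridged)
  expect_true(all(is.finite(fitc$coefficients)))
})

test_that("LOOCV LDA matches an independent fold-by-fold oracle", {
  skip_if_not_installed("MASS")
  set.seed(41)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("EMT", "other"), 10)
  x[y == "EMT", ] <- x[y == "EMT", ] + 1
  mine <- loocv_auc(x, y)
  # oracle: MASS::lda refit per fold, held-out posterior as the score
  post <- vapply(1:20, function(i) {
    fit <- MASS::lda(x[-i, , drop = FALSE], grouping = factor(y[-i]))
    predict(fit, x[i, , drop = FALSE])$posterior[, "EMT"]
  }, numeric(1))
  oracle <- roc_auc(post, y)$auc
  expect_equal(mine, oracle, tolerance = 1e-10)

  xs <- matrix(c(rnorm(10, 5), rnorm(10, -5)), ncol = 1,
               dimnames = list(NULL, "f"))
  expect_equal(loocv_auc(xs, rep(c("EMT", "other"), each = 10)), 1)
})

test_that("the combination search is exhaustive and finds the planted pair", {
  set.seed(42)
  n <- 120
  lab <- rep(c("EMT", "other"), each = n / 2)
  decoys <- matrix(rnorm(10 * n), 10, n)
  planted <- rbind(ifelse(lab == "EMT", 1.2, -1.2) + rnorm(n, 0, 1),
                   ifelse(lab == "EMT", -1.2, 1.2) + rnorm(n, 0, 1))
  m <- rbind(planted, decoys)
  rownames(m) <- c("mirP1", "mirP2", sprintf("mirD%02d", 1:10))
  colnames(m) <- sprintf("s%03d", 1:n)
  set.seed(43)
  res <- search_mirna_combinations(m, lab, rownames(m), max_size = 2)
  expect_setequal(res$combination, c("mirP1", "mirP2"))
  expect_gte(res$heldout_auc, 0.9)
  # exhaustiveness: the winner's LOOCV AUC is the maximum over all combos
  expect_equal(res$training_loocv_auc, max(res$all_results$loocv_auc))
  expect_equal(nrow(res$all_results), 12 + choose(12, 2))

  set.seed(44)
  res1 <- search_mirna_combinations(m, lab, rownames(m), max_size = 1)
  expect_length(res1$combination, 1L)
  expect_error(search_mirna_combinations(m, lab, "mirP1"), "at least 2")
})
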