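#' Logistic-regression motif classifier
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()], tolerance
#' 1e-8, up to 100 iterations) of class membership on a small feature set
#' (typically the three members of a motif). Complete separation is
#' detected by coefficient divergence or non-convergence; in that case the
#' model is refit with a tiny L2 ridge (lambda = 1e-6) and flagged.
#'
#' @param x samples x features numeric matrix.
#' @param labels per-sample class labels; `"EMT"` (or `1`/`TRUE`) is the
#'   positive class.
#' @return object of class `logistic_model`: `feature_ids`, `coefficients`,
#'   `intercept`, `converged`, `separation`.
#' @export
logistic_fit <- function(x, labels) {
  x <- as.matrix(x)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < 5L) stop("each class needs at least 5 samples")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100L)))
  coefs <- fit$coefficients
  separation <- !fit$converged || any(abs(coefs) > 15)
  if (separation) coefs <- ridge_logistic(x, y, lambda = 1e-6)
  structure(list(feature_ids = colnames(x),
                 coefficients = stats::setNames(coefs[-1L], colnames(x)),
                 intercept = unname(coefs[1L]),
                 converged = fit$converged, separation = separation),
            class = "logistic_model")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(labels == "EMT" | labels == "tumor" | labels == "1")
}

# ridge-penalized logistic IRLS fallback for separated data
ridge_logistic <- function(x, y, lambda = 1e-6, maxit = 100L, tol = 1e-8) {
  X <- cbind(1, x)
  b <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1L, 1L] <- 0
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    bn <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  drop(b)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model:",
      paste(sprintf("%.4f*%s", x$coefficients, x$feature_ids), collapse = " + "),
      sprintf("+ %.4f", x$intercept),
      if (x$separation) "[separation: ridged]" else "", "\n")
  invisible(x)
}

#' Predicted positive-class probability
#' @param object a `logistic_model`.
#' @param newx samples x features matrix containing the model's features.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.logistic_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)[, object$feature_ids, drop = FALSE]
  stats::plogis(object$intercept + drop(newx %*% object$coefficients))
}

#' Empirical ROC curve and AUC
#'
#' AUC by the trapezoidal rule over the empirical ROC, which equals the
#' tie-corrected Mann-Whitney statistic U / (n1 n2).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels class labels; positive per [logistic_fit()] conventions.
#' @return object of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n0, numeric(1))
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Frozen-model validation across cohorts
#'
#' Applies a fitted [logistic_fit()] model (coefficients frozen, never
#' refit) to each cohort in turn and reports the per-cohort ROC/AUC.
#' Cohort normalization is the caller's responsibility: the intended
#' protocol is joint [pool_and_normalize()] for the training + validation
#' pair and independent [quantile_normalize()] for any further cohort (see
#' [motif_diagnostics()] for the full orchestration).
#'
#' @param model a `logistic_model`.
#' @param cohorts named list; each element a list with `expr` (features x
#'   samples matrix) and `labels`.
#' @return named list of `roc_result` objects.
#' @export
cross_cohort_validate <- function(model, cohorts) {
  lapply(cohorts, function(co) {
    m <- as_plain_matrix(co$expr)
    missing <- setdiff(model$feature_ids, rownames(m))
    if (length(missing))
      stop("model feature(s) missing from cohort: ",
           paste(missing, collapse = ", "))
    scores <- predict(model, t(m[model$feature_ids, , drop = FALSE]))
    roc_auc(scores, co$labels)
  })
}

#' Train / validate / independent diagnostic evaluation of a motif
#'
#' Pools the training and validation cohorts over shared features,
#' quantile-normalizes them jointly, re-separates, fits the logistic model
#' on the training cohort, and evaluates the frozen model on all provided
#' cohorts; an independent cohort is quantile-normalized on its own.
#'
#' @param motif character vector of gene ids (the predictors).
#' @param train,validation lists with `expr` ([expr_matrix()]) and `labels`.
#' @param independent optional third cohort, same structure.
#' @return list: `model`, `roc` (named list of `roc_result`).
#' @export
motif_diagnostics <- function(motif, train, validation, independent = NULL) {
  pooled <- pool_and_normalize(train$expr, validation$expr)
  tr_m <- as_plain_matrix(pooled$a)[motif, , drop = FALSE]
  model <- logistic_fit(t(tr_m), train$labels)
  cohorts <- list(
    train = list(expr = pooled$a, labels = train$labels),
    validation = list(expr = pooled$b, labels = validation$labels))
  if (!is.null(independent)) {
    ind <- quantile_normalize(log2_if_counts(independent$expr))
    cohorts$independent <- list(expr = ind, labels = independent$labels)
  }
  list(model = model, roc = cross_cohort_validate(model, cohorts))
}

log2_if_counts <- function(x) {
  if (platform_of(x) == "counts")
    expr_matrix(log2(as_plain_matrix(x) + 1), "normalized")
  else x
}

#' Tumor-vs-normal split validation
#'
#' Stratified random 70/30 (by default) split of a tumor + normal cohort;
#' fits the motif logistic model on the training part and reports training
#' and held-out ROC/AUC. Reproducible given the caller's RNG state.
#'
#' @param motif gene ids used as predictors.
#' @param expr [expr_matrix()], normalized scale recommended.
#' @param tissue per-sample labels, `"tumor"` vs anything else.
#' @param split training fraction (default 0.7).
#' @return list: `model`, `roc_train`, `roc_test`, `train_ids`.
#' @export
tumor_normal_validate <- function(motif, expr, tissue, split = 0.7) {
  m <- as_plain_matrix(expr)
  y <- as_binary_labels(tissue)
  idx_train <- stratified_split(y, split)
  if (length(unique(y[idx_train])) < 2L || length(unique(y[-idx_train])) < 2L)
    stop("a tissue class is absent from one side of the split")
  xt <- t(m[motif, idx_train, drop = FALSE])
  model <- logistic_fit(xt, y[idx_train])
  sc_tr <- predict(model, xt)
  sc_te <- predict(model, t(m[motif, -idx_train, drop = FALSE]))
  list(model = model,
       roc_train = roc_auc(sc_tr, y[idx_train]),
       roc_test = roc_auc(sc_te, y[-idx_train]),
       train_ids = colnames(m)[idx_train])
}

stratified_split <- function(y, fraction) {
  idx <- unlist(lapply(unique(y), function(cl) {
    i <- which(y == cl)
    sample(i, max(1L, round(fraction * length(i))))
  }))
  sort(idx)
}

#' Candidate miRNAs for the combination search
#'
#' Differentially expressed miRNAs (BH-adjusted p at or below `padj_cut`)
#' with at least one validated target among the supplied motif genes.
#'
#' @param de_mirnas data frame from [de_test()] on the miRNA matrix.
#' @param targets target table (`mirna`, `gene`, `validated`).
#' @param motif_genes union of top-motif member gene ids.
#' @param padj_cut DE threshold (default 0.05).
#' @return character vector of miRNA ids.
#' @export
candidate_mirnas <- function(de_mirnas, targets, motif_genes, padj_cut = 0.05) {
  de_ids <- de_mirnas$feature_id[de_mirnas$padj <= padj_cut]
  val <- if (is.null(targets$validated)) rep(TRUE, nrow(targets))
         else as.logical(targets$validated)
  hit <- targets$mirna[targets$gene %in% motif_genes & val]
  intersect(de_ids, unique(hit))
}

#' Two-class Fisher linear discriminant
#'
#' Pooled within-class covariance LDA with priors from training
#' frequencies, emitting a linear index on the decision-value scale:
#' `index(x) = sum(coefficients * x) + intercept`, positive values favoring
#' the positive class. A near-singular pooled covariance is ridged
#' (lambda = 1e-6 times the mean diagonal).
#'
#' @param x samples x features matrix.
#' @param labels class labels (positive per [logistic_fit()] conventions).
#' @return object of class `lda_model`: `feature_ids`, `coefficients`,
#'   `intercept`, `training_auc`, `ridged`.
#' @export
lda_fit <- function(x, labels) {
  x <- as.matrix(x)
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) stop("each class needs at least 2 samples")
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  s1 <- stats::cov(x[y == 1L, , drop = FALSE])
  s0 <- stats::cov(x[y == 0L, , drop = FALSE])
  sp <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2)
  ridged <- FALSE
  w <- tryCatch(solve(sp, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || rcond(sp) < 1e-12) {
    sp <- sp + diag(1e-6 * mean(diag(sp)) + 1e-12, ncol(sp))
    w <- solve(sp, mu1 - mu0)
    ridged <- TRUE
  }
  intercept <- -sum(w * (mu1 + mu0) / 2) + log(n1 / n0)
  scores <- drop(x %*% w) + intercept
  structure(list(feature_ids = colnames(x),
                 coefficients = stats::setNames(drop(w), colnames(x)),
                 intercept = intercept,
                 training_auc = roc_auc(scores, y)$auc,
                 ridged = ridged),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("lda_model index:",
      paste(sprintf("(%.6f x %s)", x$coefficients, x$feature_ids),
            collapse = " + "),
      sprintf("+ %.5f", x$intercept), "\n")
  cat(sprintf("  training AUC = %.4f%s\n", x$training_auc,
              if (x$ridged) " [ridged covariance]" else ""))
  invisible(x)
}

#' LDA decision values for new samples
#' @param object an `lda_model`.
#' @param newx samples x features matrix containing the model's features.
#' @param ... unused.
#' @return numeric decision values (the linear index).
#' @export
predict.lda_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)[, object$feature_ids, drop = FALSE]
  drop(newx %*% object$coefficients) + object$intercept
}

#' Leave-one-out cross-validated LDA AUC
#'
#' Each sample is scored by an LDA trained on the remaining n - 1; the AUC
#' is computed over the n held-out decision values.
#'
#' @param x samples x features matrix (n >= 10).
#' @param labels class labels.
#' @return the LOOCV AUC.
#' @export
loocv_auc <- function(x, labels) {
  x <- as.matrix(x)
  y <- as_binary_labels(labels)
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 samples for LOOCV")
  scores <- vapply(seq_len(n), function(i) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L || min(table(yi)) < 2L)
      stop("a class vanishes in a leave-one-out fold")
    fit <- lda_fit(x[-i, , drop = FALSE], yi)
    predict(fit, x[i, , drop = FALSE])
  }, numeric(1))
  roc_auc(scores, y)$auc
}

#' Exhaustive miRNA-combination discriminant search
#'
#' Stratified 80/20 (by default) split of the samples; every candidate
#' combination of size 1..`max_size` is ranked by its LOOCV AUC on the
#' training part; the winner is refit on the full training set and scored
#' on the held-out samples. Reproducible given the caller's RNG state.
#'
#' @param expr miRNA expression matrix (miRNAs x samples).
#' @param labels per-sample class labels.
#' @param candidates candidate miRNA ids (see [candidate_mirnas()]).
#' @param max_size largest combination size (default 2).
#' @param train_fraction training split fraction (default 0.8).
#' @return object of class `mirna_search`: `model` (`lda_model`),
#'   `combination`, `training_loocv_auc`, `heldout_auc`, `all_results`
#'   (data frame of every combination's LOOCV AUC), `train_ids`.
#' @export
search_mirna_combinations <- function(expr, labels, candidates,
                                      max_size = 2L, train_fraction = 0.8) {
  if (length(candidates) < 2L) stop("need at least 2 candidate miRNAs")
  m <- as_plain_matrix(expr)
  missing <- setdiff(candidates, rownames(m))
  if (length(missing))
    stop("candidate(s) missing from expression: ", paste(missing, collapse = ", "))
  y <- as_binary_labels(labels)
  idx_train <- stratified_split(y, train_fraction)
  xt <- t(m[candidates, idx_train, drop = FALSE])
  yt <- y[idx_train]
  combos <- unlist(lapply(seq_len(max_size), function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  aucs <- vapply(combos, function(cmb) {
    tryCatch(loocv_auc(xt[, cmb, drop = FALSE], yt), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(aucs))) stop("no candidate combination was evaluable")
  res <- data.frame(combination = vapply(combos, paste, character(1),
                                         collapse = "|"),
                    size = lengths(combos), loocv_auc = aucs,
                    stringsAsFactors = FALSE)
  best <- which.max(aucs)
  winner <- combos[[best]]
  model <- lda_fit(xt[, winner, drop = FALSE], yt)
  heldout <- t(m[winner, -idx_train, drop = FALSE])
  heldout_auc <- roc_auc(predict(model, heldout), y[-idx_train])$auc
  structure(list(model = model, combination = winner,
                 training_loocv_auc = aucs[best], heldout_auc = heldout_auc,
                 all_results = res[order(-res$loocv_auc), ],
                 train_ids = colnames(m)[idx_train]),
            class = "mirna_search")
}

#' @export
print.mirna_search <- function(x, ...) {
  cat(sprintf("mirna_search: best combination %s\n",
              paste(x$combination, collapse = " + ")))
  cat(sprintf("  training LOOCV AUC = %.4f, held-out AUC = %.4f\n",
              x$training_loocv_auc, x$heldout_auc))
  print(x$model)
  invisible(x)
}
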