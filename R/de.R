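#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (p * m / rank with monotonicity
#' enforcement, clipped to 1), as provided by [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for two-class differential expression
#'
#' Per gene, fits a negative-binomial GLM with log link, design
#' intercept + class, and `log(size factor)` offsets; the gene-wise
#' dispersion is a method-of-moments estimate pooled over the two classes
#' (floored at 1e-8). The Wald statistic is the class coefficient over its
#' standard error with a two-sided normal p-value; the log2 fold change is
#' the class coefficient divided by ln 2. P-values are BH-adjusted.
#'
#' The fit is run as a vectorized IRLS across all genes simultaneously
#' (the design has only two columns), which keeps genome-scale input fast.
#'
#' All-zero genes are reported with lfc = 0, stat = 0, p = 1.
#'
#' @param counts an [expr_matrix()] with platform `"counts"`.
#' @param labels factor/character per sample; `"EMT"` is the test class,
#'   everything else the reference.
#' @param maxit,tol IRLS iteration cap and convergence tolerance.
#' @return data frame: feature_id, lfc, stat, pvalue, padj.
#' @export
nb_wald_test <- function(counts, labels, maxit = 25L, tol = 1e-8) {
  if (platform_of(counts) != "counts") stop("nb_wald_test expects counts")
  y <- as_plain_matrix(counts)
  x <- as.integer(labels == "EMT")
  if (sum(x) < 2L || sum(1 - x) < 2L)
    stop("each class needs at least 2 samples")
  sf <- size_factors(counts)
  off <- log(sf)
  q <- sweep(y, 2L, sf, "/")                       # normalized counts
  n1 <- sum(x); n0 <- length(x) - n1
  mu1 <- rowMeans(q[, x == 1L, drop = FALSE])
  mu0 <- rowMeans(q[, x == 0L, drop = FALSE])
  v1 <- apply(q[, x == 1L, drop = FALSE], 1L, stats::var)
  v0 <- apply(q[, x == 0L, drop = FALSE], 1L, stats::var)
  # pooled moment estimate of NB dispersion: Var = mu + phi mu^2
  num <- (n1 - 1) * (v1 - mu1) + (n0 - 1) * (v0 - mu0)
  den <- (n1 - 1) * mu1^2 + (n0 - 1) * mu0^2
  phi <- pmax(ifelse(den > 0, num / den, 0), 1e-8)

  eps <- 1e-8
  b0 <- log(pmax(mu0, eps))
  b1 <- log(pmax(mu1, eps)) - b0
  xr <- matrix(x, nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  offr <- matrix(off, nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  for (it in seq_len(maxit)) {
    eta <- offr + b0 + b1 * xr
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)                       # NB working weights
    z <- (eta - offr) + (y - mu) / mu              # working response
    sw  <- rowSums(w);       swx  <- rowSums(w * xr)
    swz <- rowSums(w * z);   swxz <- rowSums(w * xr * z)
    swxx <- swx                                    # x is 0/1 so x^2 = x
    det <- sw * swxx - swx^2
    det[det < 1e-300] <- 1e-300
    nb0 <- (swxx * swz - swx * swxz) / det
    nb1 <- (sw * swxz - swx * swz) / det
    nb0 <- pmin(pmax(nb0, -30), 30)                # guard divergent genes
    nb1 <- pmin(pmax(nb1, -30), 30)
    delta <- max(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0; b1 <- nb1
    if (delta < tol) break
  }
  eta <- offr + b0 + b1 * xr
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  sw <- rowSums(w); swx <- rowSums(w * xr)
  det <- sw * swx - swx^2
  det[det < 1e-300] <- 1e-300
  se <- sqrt(sw / det)                             # [ (X'WX)^-1 ]_{22}
  stat <- b1 / se
  p <- 2 * stats::pnorm(-abs(stat))
  zero <- rowSums(y) == 0
  b1[zero] <- 0; stat[zero] <- 0; p[zero] <- 1
  bad <- !is.finite(stat)
  b1[bad] <- 0; stat[bad] <- 0; p[bad] <- 1
  data.frame(feature_id = rownames(y),
             lfc = b1 / log(2),
             stat = stat,
             pvalue = p,
             padj = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Welch t-test differential expression for log-scale intensities
#'
#' The intensity-platform counterpart of [nb_wald_test()], exposed behind
#' the same result contract: per-feature two-class Welch t statistics on
#' log-scale values, with the mean difference reported directly as the log2
#' fold change.
#'
#' @param expr [expr_matrix()] on a log scale (intensity or normalized).
#' @param labels per-sample class labels; `"EMT"` vs rest.
#' @return data frame: feature_id, lfc, stat, pvalue, padj.
#' @export
welch_de_test <- function(expr, labels) {
  m <- as_plain_matrix(expr)
  x <- labels == "EMT"
  n1 <- sum(x); n0 <- sum(!x)
  if (n1 < 2L || n0 < 2L) stop("each class needs at least 2 samples")
  m1 <- rowMeans(m[, x, drop = FALSE]);  m0 <- rowMeans(m[, !x, drop = FALSE])
  v1 <- apply(m[, x, drop = FALSE], 1L, stats::var)
  v0 <- apply(m[, !x, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v0 / n0
  stat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  bad <- !is.finite(stat)
  stat[bad] <- 0; p[bad] <- 1
  data.frame(feature_id = rownames(m),
             lfc = m1 - m0,
             stat = stat,
             pvalue = p,
             padj = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Differential expression dispatch on platform
#'
#' Runs [nb_wald_test()] for count matrices and [welch_de_test()] for
#' log-scale matrices.
#' @inheritParams welch_de_test
#' @return data frame: feature_id, lfc, stat, pvalue, padj.
#' @export
de_test <- function(expr, labels) {
  if (platform_of(expr) == "counts") nb_wald_test(expr, labels)
  else welch_de_test(expr, labels)
}

#' Per-feature ROC AUC between two classes
#'
#' Mann-Whitney AUC with tie correction via average ranks: the probability
#' that a random EMT sample exceeds a random non-EMT sample. `auc` is the
#' oriented value; `auc_dirfree = max(auc, 1 - auc)` is the direction-free
#' separability used as a motif-scoring component.
#'
#' @param expr expression matrix (features x samples).
#' @param labels per-sample class labels; `"EMT"` vs rest.
#' @return data frame: feature_id, auc, auc_dirfree.
#' @export
gene_auc <- function(expr, labels) {
  m <- as_plain_matrix(expr)
  pos <- labels == "EMT"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  auc <- apply(m, 1L, function(v) {
    r <- rank(v)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  data.frame(feature_id = rownames(m),
             auc = auc,
             auc_dirfree = pmax(auc, 1 - auc),
             stringsAsFactors = FALSE)
}
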