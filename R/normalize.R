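#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median across genes of the
#' ratio of a sample's counts to the per-gene geometric mean across samples.
#' Genes with a zero count in any sample drop out of the reference (their
#' log geometric mean is -Inf) but are still scaled by the resulting factor.
#'
#' @param counts count matrix (features x samples).
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- as_plain_matrix(counts)
  if (any(colSums(m) == 0)) stop("all-zero sample column: size factor undefined")
  log_geo <- rowMeans(log(m))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no gene with all-positive counts: size factors undefined")
  apply(m[use, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - log_geo[use]))
  })
}

#' Variance-stabilizing-style transform for count data
#'
#' Divides each sample by its median-of-ratios size factor and returns
#' `log2(normalized count + 1)`. This is a transparent stand-in for a fitted
#' variance-stabilizing transform: it removes depth differences and
#' compresses the count scale so that downstream correlation and survival
#' analyses operate on roughly homoskedastic log-scale values.
#'
#' @param counts an [expr_matrix()] with platform `"counts"`.
#' @return an [expr_matrix()] with platform `"normalized"`.
#' @export
vst_transform <- function(counts) {
  if (platform_of(counts) != "counts")
    stop("vst_transform expects a counts matrix")
  sf <- size_factors(counts)
  m <- sweep(as_plain_matrix(counts), 2L, sf, "/")
  expr_matrix(log2(m + 1), "normalized")
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same marginal distribution:
#' the mean across columns of the column-sorted values. Tied values within
#' a column receive the mean of the reference values at their tied ranks.
#'
#' @param x numeric matrix or [expr_matrix()]; at least two columns.
#' @return matrix of the same shape; platform `"normalized"` if input was an
#'   `expr_matrix`.
#' @export
quantile_normalize <- function(x) {
  m <- as_plain_matrix(x)
  if (ncol(m) < 2L) {
    warning("quantile normalization of a single column is a no-op")
    return(if (inherits(x, "expr_matrix")) expr_matrix(m, "normalized") else m)
  }
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    # ties get the mean of the reference values they would have occupied
    out[, j] <- stats::ave(assigned, match(col, col), FUN = mean)
  }
  dimnames(out) <- dimnames(m)
  if (inherits(x, "expr_matrix")) expr_matrix(out, "normalized") else out
}

#' Pool two cohorts, quantile normalize jointly, and re-separate
#'
#' Implements the cross-platform protocol used before fitting diagnostic
#' models on one cohort and validating on another: the two matrices are
#' restricted to their shared features, brought to the log2 scale (counts
#' get `log2(x + 1)`, intensity/normalized values are already log-scale),
#' column-bound, quantile normalized together, and split again.
#'
#' @param a,b [expr_matrix()] objects.
#' @return list with elements `a` and `b`, the re-separated normalized
#'   matrices over the common features.
#' @export
pool_and_normalize <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (!length(common)) stop("cohorts share no features")
  to_log2 <- function(x) {
    m <- as_plain_matrix(x)[common, , drop = FALSE]
    if (platform_of(x) == "counts") log2(m + 1) else m
  }
  pooled <- cbind(to_log2(a), to_log2(b))
  qn <- quantile_normalize(pooled)
  na <- ncol(a)
  list(a = expr_matrix(qn[, seq_len(na), drop = FALSE], "normalized"),
       b = expr_matrix(qn[, -seq_len(na), drop = FALSE], "normalized"))
}

#' Flag outlying samples in PCA space
#'
#' Projects samples onto the first two principal components of the
#' expression matrix and flags those lying more than `k_sd` robust standard
#' deviations (MAD) from the component-wise median on either component.
#'
#' @param x expression matrix (features x samples), log-scale recommended.
#' @param k_sd robust-sd multiplier; default 4.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_outliers <- function(x, k_sd = 4) {
  m <- as_plain_matrix(x)
  if (ncol(m) < 3L) stop("need at least 3 samples for PCA outlier detection")
  keep <- apply(m, 1L, stats::sd) > 0
  pc <- stats::prcomp(t(m[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  flagged <- rep(FALSE, ncol(m))
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    dev <- abs(s - stats::median(s))
    scale <- stats::mad(s)
    if (scale == 0) next
    flagged <- flagged | dev > k_sd * scale
  }
  colnames(m)[flagged]
}
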