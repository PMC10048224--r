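#' Signed weighted adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with Pearson correlation across
#' samples; the diagonal is set to 0 so that row sums give network
#' connectivity. Zero-variance genes get correlation 0 to every other gene.
#'
#' @param expr expression matrix (genes x samples), log-scale.
#' @param beta soft-threshold power (>= 1).
#' @return genes x genes adjacency matrix in \[0, 1\].
#' @export
signed_adjacency <- function(expr, beta) {
  if (beta < 1) stop("beta must be >= 1")
  m <- as_plain_matrix(expr)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0                     # zero-variance genes
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 0
  a
}

#' Scan soft-threshold powers for approximate scale-free topology
#'
#' For each candidate power the connectivity distribution is binned on a
#' log10 grid and the fit R^2 of `log10 p(k)` on `log10 k` is recorded
#' together with the mean connectivity. The chosen power is the smallest
#' candidate reaching `r2_cut` (default 0.8); if none does, the candidate
#' with the largest R^2. A power can be forced via `forced` (the pipeline
#' default forces 20, matching a signed network on subtype-restricted
#' tumor expression).
#'
#' @param expr expression matrix (genes x samples).
#' @param candidates candidate powers.
#' @param r2_cut scale-free fit threshold.
#' @param forced optional fixed power overriding the scan.
#' @param n_bins connectivity histogram bins.
#' @return object of class `soft_threshold_scan` with per-power R^2 and
#'   mean connectivity and the `chosen_power`.
#' @export
pick_soft_threshold <- function(expr, candidates = 1:20, r2_cut = 0.8,
                                forced = NULL, n_bins = 10L) {
  if (!length(candidates)) stop("no candidate powers")
  m <- as_plain_matrix(expr)
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0
  s <- (1 + cc) / 2
  diag(s) <- 0
  r2 <- meank <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    k <- rowSums(s^candidates[i])
    meank[i] <- mean(k)
    k <- k[k > 0]
    br <- seq(min(log10(k)), max(log10(k)), length.out = n_bins + 1L)
    bin <- cut(log10(k), br, include.lowest = TRUE)
    freq <- tabulate(bin, nbins = n_bins)
    mid <- (br[-1] + br[-length(br)]) / 2
    use <- freq > 0
    if (sum(use) < 3L) { r2[i] <- 0; next }
    fit <- stats::lm(log10(freq[use] / sum(freq)) ~ mid[use])
    r2[i] <- summary(fit)$r.squared
  }
  chosen <- if (!is.null(forced)) {
    forced
  } else if (any(r2 >= r2_cut)) {
    candidates[which(r2 >= r2_cut)[1L]]
  } else {
    candidates[which.max(r2)]
  }
  structure(list(candidate_powers = candidates, scale_free_r2 = r2,
                 mean_connectivity = meank, chosen_power = chosen,
                 forced = !is.null(forced)),
            class = "soft_threshold_scan")
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan\n")
  print(data.frame(power = x$candidate_powers, r2 = round(x$scale_free_r2, 3),
                   mean_k = round(x$mean_connectivity, 2)), row.names = FALSE)
  cat(sprintf("chosen power: %d%s\n", x$chosen_power,
              if (x$forced) " (forced)" else ""))
  invisible(x)
}

#' Topological overlap matrix
#'
#' `w_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, `w_ii = 1`. Input must be a symmetric adjacency in \[0, 1\]
#' with zero diagonal.
#'
#' @param a adjacency matrix.
#' @return TOM similarity matrix.
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  w <- num / den
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  w
}

#' TOM dissimilarity
#' @param a adjacency matrix.
#' @return `1 - topological_overlap(a)`.
#' @export
tom_dissimilarity <- function(a) 1 - topological_overlap(a)

#' Cluster genes into modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering followed by a static branch cut
#' at `cut_frac` of the tallest merge height; clusters smaller than
#' `min_module_size` become unassigned ("grey", module 0). Modules are
#' renumbered by decreasing size. Deterministic given its input.
#'
#' @param diss square dissimilarity matrix with gene dimnames.
#' @param min_module_size smallest retained module (default 20).
#' @param cut_frac cut height as a fraction of the maximum merge height.
#' @return named integer vector gene -> module id (0 = grey).
#' @export
cluster_modules <- function(diss, min_module_size = 20L, cut_frac = 0.99) {
  genes <- rownames(diss)
  n <- nrow(diss)
  if (n < min_module_size)
    return(stats::setNames(rep(0L, n), genes))
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  labels <- stats::cutree(hc, h = cut_frac * max(hc$height))
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_module_size]
  out <- rep(0L, n)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) out[labels == keep[i]] <- i
  }
  stats::setNames(out, genes)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component (unit-norm
#' sample scores) of the row-standardized module submatrix, sign-oriented
#' to correlate positively with the module's mean standardized expression.
#'
#' @param expr expression matrix (genes x samples).
#' @param modules named integer vector gene -> module id; 0 is ignored.
#' @return list: `eigengenes` (samples x modules matrix, columns "ME<id>"),
#'   `var_explained` (per-module PC1 variance fraction).
#' @export
module_eigengenes <- function(expr, modules) {
  m <- as_plain_matrix(expr)
  ids <- sort(unique(modules[modules > 0]))
  if (!length(ids)) stop("no modules to compute eigengenes for")
  me <- matrix(NA_real_, ncol(m), length(ids),
               dimnames = list(colnames(m), paste0("ME", ids)))
  ve <- stats::setNames(numeric(length(ids)), paste0("ME", ids))
  for (i in seq_along(ids)) {
    sub <- m[names(modules)[modules == ids[i]], , drop = FALSE]
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    me[, i] <- e
    ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Module membership (kME)
#'
#' Correlation of each gene's profile with each module eigengene.
#' @param expr expression matrix (genes x samples).
#' @param eigengenes samples x modules eigengene matrix.
#' @return genes x modules correlation matrix.
#' @export
module_membership <- function(expr, eigengenes) {
  m <- as_plain_matrix(expr)
  km <- suppressWarnings(stats::cor(t(m), eigengenes))
  km[!is.finite(km)] <- 0
  km
}

#' Merge modules with close eigengenes
#'
#' Iteratively merges the pair of modules whose eigengene dissimilarity
#' `1 - cor(ME_a, ME_b)` is smallest while below `cut_height`, recomputing
#' eigengenes after every merge, until no pair is within the cut. The
#' operation is idempotent once no eigengene pair is within the cut height.
#'
#' @param expr expression matrix (genes x samples).
#' @param modules named integer vector gene -> module id.
#' @param cut_height merge threshold on eigengene dissimilarity (0.25).
#' @return named integer vector with merged, size-ordered module ids.
#' @export
merge_modules <- function(expr, modules, cut_height = 0.25) {
  repeat {
    ids <- sort(unique(modules[modules > 0]))
    if (length(ids) < 2L) break
    me <- module_eigengenes(expr, modules)$eigengenes
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    if (min(d) >= cut_height) break
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    keep <- ids[min(idx)]; drop <- ids[max(idx)]
    modules[modules == drop] <- keep
  }
  renumber_modules(modules)
}

renumber_modules <- function(modules) {
  ids <- unique(modules[modules > 0])
  if (!length(ids)) return(modules)
  sizes <- vapply(ids, function(i) sum(modules == i), integer(1))
  ord <- ids[order(-sizes, ids)]
  out <- modules
  for (i in seq_along(ord)) out[modules == ord[i]] <- i
  out
}

#' Module significance from differential expression
#'
#' The significance of a module is the mean over its member genes of
#' `-log10(padj)` from the EMT-vs-rest differential expression results;
#' genes missing from the results contribute padj = 1 and padj is floored
#' at 1e-300.
#'
#' @param modules named integer vector gene -> module id.
#' @param de data frame with `feature_id` and `padj` (see [de_test()]).
#' @return named numeric vector module id -> mean -log10(padj).
#' @export
module_significance <- function(modules, de) {
  ids <- sort(unique(modules[modules > 0]))
  if (!length(ids)) stop("no modules")
  padj <- stats::setNames(de$padj, de$feature_id)
  vapply(stats::setNames(ids, ids), function(i) {
    genes <- names(modules)[modules == i]
    p <- padj[genes]
    p[is.na(p)] <- 1
    mean(-log10(pmax(p, 1e-300)))
  }, numeric(1))
}

#' Module-trait correlations
#'
#' Pearson correlation (with two-sided p) of each module eigengene with
#' each numeric or binary-encoded clinical trait. Constant traits give
#' r = 0, p = 1.
#'
#' @param eigengenes samples x modules matrix.
#' @param traits data frame of numeric traits, rows aligned with samples.
#' @return list of matrices `r` and `p` (modules x traits).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  r <- p <- matrix(NA_real_, ncol(eigengenes), ncol(traits),
                   dimnames = list(colnames(eigengenes), names(traits)))
  for (i in seq_len(ncol(eigengenes))) {
    for (j in seq_len(ncol(traits))) {
      tr <- as.numeric(traits[[j]])
      ok <- is.finite(tr)
      if (sum(ok) < 3L || stats::sd(tr[ok]) == 0) { r[i, j] <- 0; p[i, j] <- 1; next }
      ct <- stats::cor.test(eigengenes[ok, i], tr[ok])
      r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Select the most significant module
#'
#' Argmax of [module_significance()]; ties broken by larger module size,
#' then by smaller module id.
#'
#' @param modules named integer vector gene -> module id.
#' @param significance named vector from [module_significance()].
#' @return the selected module id (integer).
#' @export
select_top_module <- function(modules, significance) {
  if (!length(significance)) stop("no modules to select from")
  ids <- as.integer(names(significance))
  sizes <- vapply(ids, function(i) sum(modules == i), integer(1))
  ord <- order(-significance, -sizes, ids)
  ids[ord[1L]]
}

#' Full module-discovery pipeline
#'
#' Signed adjacency -> TOM -> average-linkage clustering with static cut ->
#' grey-gene reassignment by module membership -> eigengene-based merging.
#' Intended to run on the EMT-subtype samples only (subset before calling,
#' or via [run_all()]).
#'
#' @param expr expression matrix (genes x samples), log-scale.
#' @param beta soft-threshold power (default 20).
#' @param min_module_size minimum module size (default 20).
#' @param merge_height eigengene merge cut height (default 0.25).
#' @param kme_reassign grey genes with |kME| at or above this are adopted
#'   by their best-matching module (default 0.5; the null kME of an
#'   unrelated gene has sd about 1/sqrt(n samples), so lower thresholds
#'   adopt correlation noise at small n).
#' @return object of class `module_assignment`: list with `modules`
#'   (gene -> id), `eigengenes`, `var_explained`, `kme`, `labels`
#'   (module id -> highest-kME gene), `beta`.
#' @export
find_modules <- function(expr, beta = 20, min_module_size = 20L,
                         merge_height = 0.25, kme_reassign = 0.5) {
  a <- signed_adjacency(expr, beta)
  d <- 1 - topological_overlap(a)
  modules <- cluster_modules(d, min_module_size = min_module_size)
  if (any(modules > 0)) {
    me <- module_eigengenes(expr, modules)
    km <- module_membership(expr, me$eigengenes)
    grey <- names(modules)[modules == 0]
    for (g in grey) {
      best <- which.max(abs(km[g, ]))
      if (abs(km[g, best]) >= kme_reassign)
        modules[g] <- as.integer(sub("^ME", "", colnames(km)[best]))
    }
    modules <- merge_modules(expr, modules, cut_height = merge_height)
    me <- module_eigengenes(expr, modules)
    km <- module_membership(expr, me$eigengenes)
    labels <- vapply(colnames(me$eigengenes), function(cn) {
      id <- as.integer(sub("^ME", "", cn))
      members <- names(modules)[modules == id]
      members[which.max(km[members, cn])]
    }, character(1))
  } else {
    me <- list(eigengenes = NULL, var_explained = NULL)
    km <- NULL
    labels <- character(0)
  }
  structure(list(modules = modules, eigengenes = me$eigengenes,
                 var_explained = me$var_explained, kme = km,
                 labels = labels, beta = beta),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(factor(x$modules))
  cat(sprintf("module_assignment: %d genes, %d modules (beta = %s)\n",
              length(x$modules), sum(names(tab) != "0"), format(x$beta)))
  print(tab)
  invisible(x)
}
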