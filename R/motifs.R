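#' Subnetwork induced on a gene set
#' @param network undirected igraph object.
#' @param genes character vector of gene ids.
#' @return the subgraph induced on `genes` intersected with the node set.
#' @export
induced_subnetwork <- function(network, genes) {
  keep <- intersect(genes, igraph::V(network)$name)
  igraph::induced_subgraph(network, keep)
}

canonical_triples <- function(mat) {
  # rows = triples; sort within row, then order rows lexicographically
  if (!nrow(mat)) return(mat)
  mat <- t(apply(mat, 1L, sort))
  mat <- unique(mat)
  mat[order(mat[, 1L], mat[, 2L], mat[, 3L]), , drop = FALSE]
}

triple_key <- function(mat)
  apply(mat, 1L, function(r) paste(sort(r), collapse = "|"))

#' Enumerate triangle motifs
#'
#' All unordered node triples with all three edges present, each reported
#' once in canonical (sorted) order.
#'
#' @param network simple undirected igraph object.
#' @return character matrix with 3 columns, one row per triangle (0 rows if
#'   none), rows in lexicographic order.
#' @export
enumerate_triangles <- function(network) {
  tri <- igraph::triangles(network)
  if (!length(tri)) {
    return(matrix(character(0), 0L, 3L,
                  dimnames = list(NULL, c("gene1", "gene2", "gene3"))))
  }
  mat <- matrix(igraph::V(network)$name[tri], ncol = 3L, byrow = TRUE)
  mat <- canonical_triples(mat)
  colnames(mat) <- c("gene1", "gene2", "gene3")
  mat
}

#' Per-motif metric components
#'
#' For each triangle: mean node degree (ND) and mean betweenness centrality
#' (BC) of its members on the motif-bearing network (the module-induced
#' subnetwork, not the global interactome), the count of members in the
#' cancer-pathway gene set (DP, 0-3), the mean direction-free per-gene ROC
#' AUC, and the mean absolute log2 fold change.
#'
#' @param triples character matrix from [enumerate_triangles()].
#' @param network the network the triangles were found in.
#' @param de data frame with `feature_id` and `lfc` (see [de_test()]).
#' @param aucs data frame with `feature_id` and `auc_dirfree`
#'   (see [gene_auc()]).
#' @param pathway_genes character vector of cancer-pathway gene ids.
#' @return data frame: gene1..gene3, nd, bc, dp, auc, abs_lfc.
#' @export
motif_metrics <- function(triples, network, de, aucs, pathway_genes) {
  nodes <- igraph::V(network)$name
  missing <- setdiff(unique(as.vector(triples)), nodes)
  if (length(missing))
    stop("motif gene(s) not in network: ", paste(missing, collapse = ", "))
  deg <- stats::setNames(igraph::degree(network), nodes)
  btw <- stats::setNames(igraph::betweenness(network, directed = FALSE), nodes)
  lfc <- stats::setNames(abs(de$lfc), de$feature_id)
  auc <- stats::setNames(aucs$auc_dirfree, aucs$feature_id)
  per_motif <- function(vals, default = NA_real_) {
    v <- matrix(vals[as.vector(triples)], ncol = 3L)
    rowMeans(v)
  }
  data.frame(gene1 = triples[, 1L], gene2 = triples[, 2L], gene3 = triples[, 3L],
             nd = per_motif(deg),
             bc = per_motif(btw),
             dp = rowSums(matrix(as.vector(triples) %in% pathway_genes, ncol = 3L)),
             auc = per_motif(auc),
             abs_lfc = per_motif(lfc),
             stringsAsFactors = FALSE)
}

#' Default weighting-scenario table
#'
#' Thirteen scenarios spanning single-criterion emphases (topology-,
#' pathway-, diagnosis- and expression-only), pairwise mixes, the uniform
#' scenario, and two tilted mixes. Columns: `id`, `w1` (topology, split
#' evenly between ND and BC), `w2` (pathway), `w3` (diagnostic AUC),
#' `w4` (expression |LFC|). Fully overridable: any data frame with these
#' columns works wherever a scenario table is accepted.
#'
#' @return 13-row data frame.
#' @export
default_scenarios <- function() {
  data.frame(
    id = paste0("s", 1:13),
    w1 = c(1, 0, 0, 0, 0.25, 0.5, 0.5, 0.5, 0,   0,   0,   0.4, 0.1),
    w2 = c(0, 1, 0, 0, 0.25, 0.5, 0,   0,   0.5, 0.5, 0,   0.2, 0.3),
    w3 = c(0, 0, 1, 0, 0.25, 0,   0.5, 0,   0.5, 0,   0.5, 0.2, 0.3),
    w4 = c(0, 0, 0, 1, 0.25, 0,   0,   0.5, 0,   0.5, 0.5, 0.2, 0.3),
    stringsAsFactors = FALSE)
}

#' Multi-objective motif scores
#'
#' For motif i and scenario j:
#' `S_ij = (w1/2) ND_i/max(ND) + (w1/2) BC_i/max(BC) + w2 DP_i/max(DP)
#'  + w3 AUC_i/max(AUC) + w4 |LFC|_i/max(|LFC|)`,
#' where each maximum is taken over the motif list. A component whose
#' maximum is 0 contributes 0 for every motif. Scores therefore lie in
#' `[0, w1 + w2 + w3 + w4]` and the component-wise maximal motif attains
#' the upper bound.
#'
#' @param metrics data frame from [motif_metrics()].
#' @param scenarios scenario table (see [default_scenarios()]).
#' @return object of class `scored_motifs`: the metrics data frame with one
#'   `score_<id>` column per scenario; attribute `max_denominators` records
#'   the maxima used.
#' @export
score_motifs <- function(metrics, scenarios = default_scenarios()) {
  if (!nrow(metrics)) stop("no motifs to score")
  mx <- c(nd = max(metrics$nd), bc = max(metrics$bc), dp = max(metrics$dp),
          auc = max(metrics$auc), abs_lfc = max(metrics$abs_lfc))
  ratio <- function(v, m) if (m > 0) v / m else rep(0, length(v))
  r_nd <- ratio(metrics$nd, mx["nd"]);   r_bc <- ratio(metrics$bc, mx["bc"])
  r_dp <- ratio(metrics$dp, mx["dp"]);   r_auc <- ratio(metrics$auc, mx["auc"])
  r_lfc <- ratio(metrics$abs_lfc, mx["abs_lfc"])
  out <- metrics
  for (i in seq_len(nrow(scenarios))) {
    s <- scenarios[i, ]
    out[[paste0("score_", s$id)]] <-
      s$w1 / 2 * r_nd + s$w1 / 2 * r_bc + s$w2 * r_dp + s$w3 * r_auc + s$w4 * r_lfc
  }
  structure(out, max_denominators = mx,
            class = c("scored_motifs", class(out)))
}

#' @export
print.scored_motifs <- function(x, ...) {
  sc <- grep("^score_", names(x))
  cat(sprintf("scored_motifs: %d motifs, %d scenarios\n", nrow(x), length(sc)))
  best <- order(-rowMeans(as.data.frame(x)[, sc, drop = FALSE]))
  print(utils::head(as.data.frame(x)[best, ], 5L), row.names = FALSE)
  invisible(x)
}

#' Top motifs across scenarios, deduplicated
#'
#' Takes the `top_k` motifs of every scenario (by score, ties broken by
#' higher mean node degree, then lexicographic gene triple), unions across
#' scenarios and removes redundant entries (identical node sets); motifs
#' sharing two of three genes are kept as distinct.
#'
#' @param scored `scored_motifs` object from [score_motifs()].
#' @param top_k motifs per scenario (default 10).
#' @return data frame of the selected motifs (metrics + score columns).
#' @export
rank_and_select <- function(scored, top_k = 10L) {
  df <- as.data.frame(scored)
  sc <- grep("^score_", names(df), value = TRUE)
  if (!length(sc)) stop("no scenario score columns")
  keys <- character(0)
  for (col in sc) {
    ord <- order(-df[[col]], -df$nd, df$gene1, df$gene2, df$gene3)
    take <- ord[seq_len(min(top_k, nrow(df)))]
    keys <- union(keys, triple_key(as.matrix(df[take, c("gene1", "gene2", "gene3")])))
  }
  all_keys <- triple_key(as.matrix(df[, c("gene1", "gene2", "gene3")]))
  sel <- df[all_keys %in% keys & !duplicated(all_keys), ]
  rownames(sel) <- NULL
  sel
}
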