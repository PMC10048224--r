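#' Build the mixed miRNA-mRNA interaction network
#'
#' Nodes are the union of the top-motif member genes and the candidate
#' miRNAs; edges are the protein-protein interactions among the motif genes
#' plus the validated miRNA-to-motif-gene target pairs. The graph is simple
#' and undirected, with node attribute `type` ("mRNA"/"miRNA") and edge
#' attribute `edge_type` ("ppi"/"target"); miRNA-miRNA edges cannot occur
#' by construction.
#'
#' @param ppi undirected igraph of protein-protein interactions.
#' @param targets target table (`mirna`, `gene`, optional `validated`).
#' @param motif_genes member genes of the selected motifs.
#' @param mirnas candidate miRNA ids.
#' @return igraph object.
#' @export
build_mixed_network <- function(ppi, targets, motif_genes, mirnas) {
  sub <- induced_subnetwork(ppi, motif_genes)
  el_ppi <- igraph::as_edgelist(sub)
  val <- if (is.null(targets$validated)) rep(TRUE, nrow(targets))
         else as.logical(targets$validated)
  tt <- targets[val & targets$mirna %in% mirnas &
                  targets$gene %in% motif_genes, , drop = FALSE]
  el_tgt <- unique(cbind(tt$mirna, tt$gene))
  el <- rbind(el_ppi, el_tgt)
  edge_type <- rep(c("ppi", "target"), c(nrow(el_ppi), nrow(el_tgt)))
  nodes <- unique(c(motif_genes, mirnas))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1L], to = el[, 2L], edge_type = edge_type,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes,
                          type = ifelse(nodes %in% mirnas, "miRNA", "mRNA"),
                          stringsAsFactors = FALSE))
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Latora (harmonic) closeness
#'
#' `C(v) = sum over u != v of 1 / d(v, u)` with `1/Inf = 0`, so the measure
#' is finite on disconnected graphs and isolated nodes score 0.
#'
#' @param network igraph object.
#' @return named numeric vector node -> centrality.
#' @export
latora_closeness <- function(network) {
  d <- igraph::distances(network)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv)
}

# leverage centrality: mean over neighbors of (k_v - k_u)/(k_v + k_u)
leverage_centrality <- function(g) {
  deg <- igraph::degree(g)
  vapply(seq_along(deg), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (!length(nb)) return(0)
    mean((deg[v] - deg[nb]) / (deg[v] + deg[nb]))
  }, numeric(1))
}

centrality_registry <- function() {
  list(
    degree = function(g) igraph::degree(g),
    betweenness = function(g) igraph::betweenness(g, directed = FALSE),
    closeness = function(g) {
      # per-component classic closeness; isolated nodes 0
      cl <- suppressWarnings(igraph::closeness(g, mode = "all"))
      cl[!is.finite(cl)] <- 0
      cl
    },
    latora_closeness = function(g) latora_closeness(g),
    eigenvector = function(g) igraph::eigen_centrality(g)$vector,
    pagerank = function(g) igraph::page_rank(g)$vector,
    katz = function(g) igraph::alpha_centrality(
      g, alpha = 0.9 / max(1, max(abs(eigen(
        igraph::as_adjacency_matrix(g, sparse = FALSE),
        only.values = TRUE)$values)))),
    subgraph = function(g) igraph::subgraph_centrality(g),
    clustering = function(g) {
      tr <- igraph::transitivity(g, type = "local", isolates = "zero")
      tr
    },
    kcore = function(g) igraph::coreness(g),
    eccentricity = function(g) {
      # inverted so that larger = more central, finite per component
      ec <- igraph::eccentricity(g)
      ifelse(ec > 0, 1 / ec, 0)
    },
    leverage = function(g) leverage_centrality(g)
  )
}

#' Node centrality profile over a measure registry
#'
#' Computes every requested centrality measure for every node. The default
#' registry ships 12 measures (degree, betweenness, classic and Latora
#' closeness, eigenvector, PageRank, Katz, subgraph, local clustering
#' coefficient, k-core index, inverse eccentricity, leverage); further
#' measures can be supplied as named functions taking an igraph object.
#'
#' @param network igraph object.
#' @param measures character vector of registry names, or a named list of
#'   functions; default: all registry measures.
#' @return object of class `centrality_profile`: `values` (nodes x
#'   measures matrix), `scaled` (z-scored columns), `measures`.
#' @export
compute_centralities <- function(network, measures = NULL) {
  reg <- centrality_registry()
  fns <- if (is.null(measures)) {
    reg
  } else if (is.character(measures)) {
    unknown <- setdiff(measures, names(reg))
    if (length(unknown))
      stop("unknown centrality measure(s): ", paste(unknown, collapse = ", "))
    reg[measures]
  } else measures
  vals <- vapply(fns, function(f) {
    v <- f(network)
    v <- as.numeric(v)
    v[!is.finite(v)] <- 0
    v
  }, numeric(igraph::vcount(network)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  rownames(vals) <- igraph::V(network)$name
  scaled <- scale(vals)
  scaled[!is.finite(scaled)] <- 0
  structure(list(values = vals, scaled = scaled, measures = colnames(vals)),
            class = "centrality_profile")
}

#' @export
print.centrality_profile <- function(x, ...) {
  cat(sprintf("centrality_profile: %d nodes x %d measures\n",
              nrow(x$values), length(x$measures)))
  invisible(x)
}

#' PCA-based selection of the most representative centrality measure
#'
#' Standardizes each measure, runs PCA on the node x measure matrix, and
#' picks the measure with the largest squared loading (contribution) on the
#' first principal component; ties broken by measure-name order. Constant
#' measure columns are dropped with a warning.
#'
#' @param profile a `centrality_profile`.
#' @return list: `chosen_measure`, `pc1_loadings` (named, over retained
#'   measures), `contributions` (squared loadings).
#' @export
pca_select_centrality <- function(profile) {
  v <- profile$values
  if (ncol(v) < 2L) stop("need at least 2 measures")
  if (nrow(v) < 3L) stop("need at least 3 nodes")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant measure column(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
  }
  if (ncol(v) < 2L) stop("fewer than 2 non-constant measures")
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1L]
  contrib <- load1^2
  # float-tolerant tie handling so duplicated measures fall back to name order
  ord <- order(-round(contrib, 10L), names(contrib))
  list(chosen_measure = names(contrib)[ord[1L]],
       pc1_loadings = load1, contributions = contrib)
}

#' Top central nodes
#' @param values named numeric centrality vector.
#' @param k number of nodes (default 10); must not exceed the node count.
#' @return character vector of the k highest-scoring nodes, ties broken by
#'   name order.
#' @export
top_central_nodes <- function(values, k = 10L) {
  if (k > length(values)) stop("k exceeds the number of nodes")
  names(values)[order(-values, names(values))][seq_len(k)]
}
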