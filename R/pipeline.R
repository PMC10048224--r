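#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis. The default
#' is a fully synthetic run at desk scale (see [synthetic_config()]).
#'
#' @param syn_config a [synthetic_config()]; its seed is overridden by
#'   `seed` so that a single root seed drives the whole run.
#' @param beta soft-threshold power for module discovery (default 20).
#' @param min_module_size minimum module size (default 20).
#' @param merge_height eigengene merge cut height (default 0.25).
#' @param scenarios motif weighting-scenario table
#'   (default [default_scenarios()]).
#' @param top_k motifs kept per scenario (default 10).
#' @param fraction high/low expression quantile (default 0.4).
#' @param min_per_group,min_total motif sample-size filter (30, 100).
#' @param top_hr_k depth of the per-cohort top-HR lists (default 5).
#' @param mirna_max_size largest miRNA combination (default 2).
#' @param mirna_train_fraction miRNA search training split (default 0.8).
#' @param padj_cut DE threshold for miRNA candidacy (default 0.05).
#' @param seed root seed; every stage derives its RNG stream from it.
#' @param verbose log stage progress to stderr.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(syn_config = synthetic_config(),
                            beta = 20, min_module_size = 20L,
                            merge_height = 0.25,
                            scenarios = default_scenarios(), top_k = 10L,
                            fraction = 0.4, min_per_group = 30L,
                            min_total = 100L, top_hr_k = 5L,
                            mirna_max_size = 2L,
                            mirna_train_fraction = 0.8,
                            padj_cut = 0.05, seed = 1L, verbose = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[emtmotif] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-data generation (or consumption of a
#' supplied study), normalization, EMT-vs-rest differential expression,
#' module discovery on the EMT-subtype samples of the primary cohort,
#' selection of the most significant module, reconstruction of its PPI
#' subnetwork, triangle enumeration, multi-objective scoring and top-motif
#' selection, per-motif survival analysis in both cohorts with the
#' cross-cohort top-HR consistency filter, cross-cohort logistic
#' diagnostics per motif, the miRNA candidate filter and LDA/LOOCV
#' combination search, and mixed-network centrality analysis.
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-built study (as returned by
#'   [generate_study()], or an equivalent list built from files); when NULL
#'   the synthetic study configured in `config` is generated.
#' @return object of class `emt_report` holding every stage's results.
#' @export
run_all <- function(config = pipeline_config(), study = NULL) {
  v <- config$verbose
  if (is.null(study)) {
    sc <- config$syn_config
    sc$seed <- as.integer(config$seed)
    study <- stage("simulate", v, generate_study(sc))
  }
  co1 <- study$cohorts[[1L]]
  co2 <- study$cohorts[[2L]]
  need <- c("sample_id", "subtype", "age", "sex", "time", "event")
  for (co in list(co1, co2)) {
    miss <- setdiff(need, names(co$ann))
    if (length(miss))
      stop("stage 'input': annotation column(s) missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }

  norm1 <- stage("normalize", v, {
    if (platform_of(co1$expr) == "counts") vst_transform(co1$expr) else co1$expr
  })
  norm2 <- if (platform_of(co2$expr) == "counts") vst_transform(co2$expr) else co2$expr

  de <- stage("de", v, de_test(co1$expr, co1$ann$subtype))
  aucs <- stage("auc", v, gene_auc(norm1, co1$ann$subtype))

  modules <- stage("modules", v, {
    emt_ids <- co1$ann$sample_id[co1$ann$subtype == "EMT"]
    expr_emt <- expr_matrix(as_plain_matrix(norm1)[, emt_ids, drop = FALSE],
                            "normalized")
    find_modules(expr_emt, beta = config$beta,
                 min_module_size = config$min_module_size,
                 merge_height = config$merge_height)
  })
  significance <- stage("module_significance", v,
                        module_significance(modules$modules, de))
  top_module <- stage("select_module", v,
                      select_top_module(modules$modules, significance))
  module_genes <- names(modules$modules)[modules$modules == top_module]

  trait_cor <- stage("module_traits", v, {
    emt_ids <- rownames(modules$eigengenes)
    ann_emt <- co1$ann[match(emt_ids, co1$ann$sample_id), ]
    module_trait_correlation(modules$eigengenes,
                             data.frame(age = ann_emt$age,
                                        male = as.numeric(ann_emt$sex == "male")))
  })

  subnet <- stage("induced_ppi", v, induced_subnetwork(study$ppi, module_genes))
  triangles <- stage("triangles", v, enumerate_triangles(subnet))
  if (!nrow(triangles))
    stop("stage 'triangles': no triangle motif in the module subnetwork",
         call. = FALSE)
  metrics <- stage("motif_metrics", v,
                   motif_metrics(triangles, subnet, de, aucs,
                                 study$config$pathway_genes %||%
                                   attr(study, "pathway_genes") %||% character(0)))
  scored <- stage("score", v, score_motifs(metrics, config$scenarios))
  selected <- stage("select_motifs", v, rank_and_select(scored, config$top_k))
  sel_mat <- as.matrix(selected[, c("gene1", "gene2", "gene3")])

  surv1 <- stage("survival_cohort1", v,
                 motif_survival(norm1, co1$ann, sel_mat, config$fraction,
                                config$min_per_group, config$min_total))
  surv2 <- stage("survival_cohort2", v,
                 motif_survival(norm2, co2$ann, sel_mat, config$fraction,
                                config$min_per_group, config$min_total))
  consistent <- stage("consistency", v,
                      consistent_top_motifs(surv1, surv2, config$top_hr_k))

  diagnostics <- stage("diagnostics", v, {
    res <- lapply(seq_len(nrow(sel_mat)), function(i) {
      motif <- sel_mat[i, ]
      d <- tryCatch(
        motif_diagnostics(motif,
                          train = list(expr = co1$expr,
                                       labels = co1$ann$subtype),
                          validation = list(expr = co2$expr,
                                            labels = co2$ann$subtype)),
        error = function(e) NULL)
      if (is.null(d)) return(NULL)
      data.frame(motif = paste(motif, collapse = "|"),
                 auc_train = d$roc$train$auc,
                 auc_validation = d$roc$validation$auc,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, res)
    tab[order(-tab$auc_validation), ]
  })

  mirna <- stage("mirna_search", v, {
    de_mir <- de_test(co1$mirna, co1$ann$subtype)
    cand <- candidate_mirnas(de_mir, study$targets,
                             unique(as.vector(sel_mat)), config$padj_cut)
    if (length(cand) < 2L)
      list(candidates = cand, search = NULL, de = de_mir)
    else {
      set.seed(config$seed + 40000L)
      list(candidates = cand,
           search = search_mirna_combinations(
             co1$mirna, co1$ann$subtype, cand,
             max_size = config$mirna_max_size,
             train_fraction = config$mirna_train_fraction),
           de = de_mir)
    }
  })

  centrality <- stage("centrality", v, {
    g <- build_mixed_network(study$ppi, study$targets,
                             unique(as.vector(sel_mat)), mirna$candidates)
    prof <- compute_centralities(g)
    sel <- pca_select_centrality(prof)
    vals <- stats::setNames(prof$values[, sel$chosen_measure],
                            rownames(prof$values))
    list(network = g, profile = prof, chosen_measure = sel$chosen_measure,
         pc1_contributions = sel$contributions,
         top_nodes = top_central_nodes(vals, min(10L, length(vals))))
  })

  structure(list(config = config, study = study, de = de, aucs = aucs,
                 modules = modules, significance = significance,
                 top_module = top_module, module_genes = module_genes,
                 trait_cor = trait_cor, subnetwork = subnet,
                 triangles = triangles, scored = scored, selected = selected,
                 survival = list(cohort1 = surv1, cohort2 = surv2,
                                 consistent = consistent),
                 diagnostics = diagnostics, mirna = mirna,
                 centrality = centrality, seed = config$seed),
            class = "emt_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.emt_report <- function(x, ...) {
  cat("EMT-subtype motif analysis report\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  modules: %d (top module M%d, %d genes, significance %.2f)\n",
              length(unique(x$modules$modules[x$modules$modules > 0])),
              x$top_module, length(x$module_genes),
              x$significance[as.character(x$top_module)]))
  cat(sprintf("  triangles in module subnetwork: %d; selected motifs: %d\n",
              nrow(x$triangles), nrow(x$selected)))
  cat(sprintf("  cross-cohort consistent top motifs: %s\n",
              if (length(x$survival$consistent))
                paste(x$survival$consistent, collapse = ", ") else "(none)"))
  if (!is.null(x$diagnostics) && nrow(x$diagnostics))
    cat(sprintf("  best diagnostic motif: %s (validation AUC %.3f)\n",
                x$diagnostics$motif[1L], x$diagnostics$auc_validation[1L]))
  if (!is.null(x$mirna$search))
    cat(sprintf("  miRNA combination: %s (LOOCV %.3f, held-out %.3f)\n",
                paste(x$mirna$search$combination, collapse = " + "),
                x$mirna$search$training_loocv_auc,
                x$mirna$search$heldout_auc))
  cat(sprintf("  centrality measure: %s; top nodes: %s\n",
              x$centrality$chosen_measure,
              paste(utils::head(x$centrality$top_nodes, 5L), collapse = ", ")))
  invisible(x)
}
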