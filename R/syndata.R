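#' Synthetic multi-cohort study configuration
#'
#' Bundles every parameter of the synthetic-data generator that emulates
#' the statistical structure of a two-cohort EMT-subtype expression study:
#' block co-expression driven by latent module factors, an expression shift
#' planted on the first ("EMT") module in EMT-labeled samples, negative
#' binomial counts or Gaussian log-intensities by platform, a background +
#' planted-triangle interaction network, proportional-hazards survival tied
#' to expression with age/sex covariates, and a miRNA layer that represses
#' its targets with a planted discriminative pair.
#'
#' Defaults are the desk-scale study conditions: 2,000 genes, 150 miRNAs,
#' two cohorts of 150 samples (counts + intensity platforms), EMT fraction
#' 0.3, five planted modules (sizes 100/80/60/50/40) with factor loadings
#' giving within-block correlations around 0.7, EMT effect of 2 log2 units.
#'
#' @param n_genes,n_mirnas feature counts.
#' @param cohort_sizes samples per cohort.
#' @param platforms per-cohort platform tags (`"counts"`/`"intensity"`).
#' @param emt_fraction fraction of EMT-subtype samples.
#' @param module_plan data frame with `size`, `loading_mean`, `loading_sd`;
#'   the first row is the planted EMT module.
#' @param emt_effect_lfc log2 shift added to EMT-module genes in EMT
#'   samples before platform noise.
#' @param nb_dispersion negative-binomial dispersion for count cohorts.
#' @param intensity_noise_sd additive noise sd for log-intensity cohorts.
#' @param libsize_sd sd of log-normal library-size factors (count cohorts).
#' @param base_range range of baseline log2 expression, drawn uniformly.
#' @param ppi_background_density Bernoulli probability of background edges.
#' @param planted_motifs character matrix (rows = triples) forced into
#'   triangles; default: two triples from the EMT module.
#' @param pathway_genes cancer-pathway gene-id set; default: the planted
#'   motif genes plus every 20th gene.
#' @param survival_betas named log-hazard coefficients on standardized
#'   expression; default 0.5 on each gene of the first planted motif.
#' @param age_beta,sex_beta log-hazard coefficients on z-scored age and
#'   male sex.
#' @param baseline_hazard exponential baseline event rate.
#' @param censor_rate independent exponential censoring rate (0 = none).
#' @param mirna_target_map data frame `mirna`, `gene`, `strength`; default:
#'   miRNA k represses genes 3(k-1)+1 .. 3k with the default strength.
#' @param mirna_strength default repression strength.
#' @param mirna_noise_sd miRNA additive noise sd.
#' @param discriminative_mirnas planted pair of miRNA ids.
#' @param discriminative_shifts per-miRNA mean shift in EMT samples.
#' @param seed root RNG seed; all generator randomness derives from it.
#' @return object of class `syn_config` (a validated list).
#' @export
synthetic_config <- function(n_genes = 2000L, n_mirnas = 150L,
                             cohort_sizes = c(150L, 150L),
                             platforms = c("counts", "intensity"),
                             emt_fraction = 0.3,
                             module_plan = data.frame(
                               size = c(100L, 80L, 60L, 50L, 40L),
                               loading_mean = 0.6, loading_sd = 0.1),
                             emt_effect_lfc = 2,
                             nb_dispersion = 0.05,
                             intensity_noise_sd = 0.3,
                             libsize_sd = 0.2,
                             base_range = c(4, 9),
                             ppi_background_density = 0.02,
                             planted_motifs = NULL,
                             pathway_genes = NULL,
                             survival_betas = NULL,
                             age_beta = 0.3, sex_beta = 0.3,
                             baseline_hazard = 0.01,
                             censor_rate = 0.005,
                             mirna_target_map = NULL,
                             mirna_strength = 0.3,
                             mirna_noise_sd = 0.7,
                             discriminative_mirnas = NULL,
                             discriminative_shifts = c(1.5, -1.5),
                             seed = 1L) {
  stopifnot(n_genes > 0, n_mirnas >= 0, all(cohort_sizes > 0),
            emt_fraction > 0, emt_fraction < 1,
            nb_dispersion > 0, censor_rate >= 0, baseline_hazard > 0,
            length(platforms) == length(cohort_sizes),
            all(platforms %in% c("counts", "intensity")))
  if (sum(module_plan$size) > n_genes)
    stop("module sizes exceed the gene count")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  mirna_ids <- if (n_mirnas > 0) sprintf("mir%03d", seq_len(n_mirnas)) else character(0)
  module1 <- gene_ids[seq_len(module_plan$size[1L])]
  if (is.null(planted_motifs)) {
    planted_motifs <- rbind(module1[1:3], module1[4:6])
  }
  planted_motifs <- as.matrix(planted_motifs)
  if (!all(planted_motifs %in% module1))
    stop("planted motif genes must belong to the planted EMT module")
  if (is.null(pathway_genes))
    pathway_genes <- unique(c(as.vector(planted_motifs),
                              gene_ids[seq(1L, n_genes, by = 20L)]))
  if (is.null(survival_betas))
    survival_betas <- stats::setNames(rep(0.5, 3L), planted_motifs[1L, ])
  if (is.null(mirna_target_map) && n_mirnas > 0) {
    tg <- ((seq_len(n_mirnas) - 1L) * 3L) %% n_genes
    mirna_target_map <- data.frame(
      mirna = rep(mirna_ids, each = 3L),
      gene = gene_ids[(rep(tg, each = 3L) + 1:3 - 1L) %% n_genes + 1L],
      strength = mirna_strength,
      stringsAsFactors = FALSE)
  }
  if (!is.null(mirna_target_map) &&
      !all(mirna_target_map$gene %in% gene_ids))
    stop("unknown target gene id in mirna_target_map")
  if (is.null(discriminative_mirnas) && n_mirnas >= 2L)
    discriminative_mirnas <- mirna_ids[1:2]
  structure(list(
    n_genes = n_genes, n_mirnas = n_mirnas, cohort_sizes = cohort_sizes,
    platforms = platforms, emt_fraction = emt_fraction,
    module_plan = module_plan, emt_effect_lfc = emt_effect_lfc,
    nb_dispersion = nb_dispersion, intensity_noise_sd = intensity_noise_sd,
    libsize_sd = libsize_sd, base_range = base_range,
    ppi_background_density = ppi_background_density,
    planted_motifs = planted_motifs, pathway_genes = pathway_genes,
    survival_betas = survival_betas, age_beta = age_beta,
    sex_beta = sex_beta, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, mirna_target_map = mirna_target_map,
    mirna_strength = mirna_strength, mirna_noise_sd = mirna_noise_sd,
    discriminative_mirnas = discriminative_mirnas,
    discriminative_shifts = discriminative_shifts,
    gene_ids = gene_ids, mirna_ids = mirna_ids, seed = as.integer(seed)),
    class = "syn_config")
}

#' @export
print.syn_config <- function(x, ...) {
  cat(sprintf(paste0("syn_config: %d genes, %d miRNAs, cohorts [%s], ",
                     "EMT fraction %.2f, effect %.1f log2, seed %d\n"),
              x$n_genes, x$n_mirnas,
              paste(x$cohort_sizes, x$platforms, collapse = ", "),
              x$emt_fraction, x$emt_effect_lfc, x$seed))
  invisible(x)
}

# gene-level parameters shared across cohorts, derived from the root seed
gene_params <- function(config) {
  set.seed(config$seed)
  base <- stats::runif(config$n_genes, config$base_range[1L],
                       config$base_range[2L])
  module <- integer(config$n_genes)
  loading <- numeric(config$n_genes)
  at <- 0L
  for (i in seq_len(nrow(config$module_plan))) {
    sz <- config$module_plan$size[i]
    idx <- at + seq_len(sz)
    module[idx] <- i
    loading[idx] <- stats::rnorm(sz, config$module_plan$loading_mean[i],
                                 config$module_plan$loading_sd[i])
    at <- at + sz
  }
  names(module) <- names(loading) <- names(base) <- config$gene_ids
  list(base = base, module = module, loading = loading)
}

#' Truth labels of the synthetic study
#'
#' @param config a [synthetic_config()].
#' @return list: `module_labels` (gene -> planted module id, 0 =
#'   background), `de_genes` (EMT-module genes with their true log2 fold
#'   change), `planted_motifs`, `survival_betas`, `discriminative_mirnas`.
#' @export
synthetic_truth <- function(config) {
  gp <- gene_params(config)
  emt_genes <- names(gp$module)[gp$module == 1L]
  list(module_labels = gp$module,
       de_genes = stats::setNames(rep(config$emt_effect_lfc,
                                      length(emt_genes)), emt_genes),
       planted_motifs = config$planted_motifs,
       survival_betas = config$survival_betas,
       discriminative_mirnas = config$discriminative_mirnas)
}

#' Generate one cohort's expression matrix and annotations
#'
#' Gene profiles follow `base + loading * module factor` on the log2 scale,
#' EMT samples get `+ emt_effect_lfc` on EMT-module genes, then platform
#' noise is applied: counts are drawn NB(mean = 2^signal * library factor,
#' dispersion) with log-normal library-size factors, intensities are the
#' signal plus Gaussian noise. Age is Normal(62, 11) truncated to
#' \[30, 90\]; sex is Bernoulli(0.6) male. Identical config and
#' cohort_index reproduce the cohort byte for byte.
#'
#' @param config a [synthetic_config()].
#' @param cohort_index which cohort (1-based).
#' @param platform override of the configured platform tag.
#' @return list: `expr` ([expr_matrix()]), `ann` (annotation data frame;
#'   `time`/`event` are NA until [generate_survival()]).
#' @export
generate_cohort <- function(config, cohort_index = 1L,
                            platform = config$platforms[cohort_index]) {
  if (cohort_index > length(config$cohort_sizes))
    stop("cohort_index exceeds the configured number of cohorts")
  if (!platform %in% c("counts", "intensity"))
    stop("invalid platform tag: ", platform)
  n <- config$cohort_sizes[cohort_index]
  gp <- gene_params(config)
  set.seed(config$seed + 1000L * cohort_index)
  sample_ids <- sprintf("c%d_s%03d", cohort_index, seq_len(n))
  n_emt <- round(config$emt_fraction * n)
  subtype <- sample(c(rep("EMT", n_emt),
                      sample(c("MSI", "TP53+", "TP53-"), n - n_emt,
                             replace = TRUE)))
  is_emt <- subtype == "EMT"
  n_mod <- nrow(config$module_plan)
  factors <- matrix(stats::rnorm(n_mod * n), n_mod, n)
  signal <- matrix(gp$base, config$n_genes, n)
  in_mod <- gp$module > 0L
  signal[in_mod, ] <- signal[in_mod, , drop = FALSE] +
    gp$loading[in_mod] * factors[gp$module[in_mod], , drop = FALSE]
  emt_gene <- gp$module == 1L
  signal[emt_gene, is_emt] <- signal[emt_gene, is_emt, drop = FALSE] +
    config$emt_effect_lfc
  if (platform == "counts") {
    libf <- exp(stats::rnorm(n, 0, config$libsize_sd))
    mu <- sweep(2^signal, 2L, libf, "*")
    vals <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow(mu), ncol(mu))
  } else {
    vals <- signal + matrix(stats::rnorm(length(signal), 0,
                                         config$intensity_noise_sd),
                            nrow(signal), ncol(signal))
  }
  dimnames(vals) <- list(config$gene_ids, sample_ids)
  age <- stats::rnorm(n, 62, 11)
  while (any(bad <- age < 30 | age > 90)) age[bad] <- stats::rnorm(sum(bad), 62, 11)
  ann <- data.frame(sample_id = sample_ids, subtype = subtype,
                    age = round(age, 1),
                    sex = ifelse(stats::rbinom(n, 1L, 0.6) == 1L,
                                 "male", "female"),
                    time = NA_real_, event = NA_integer_,
                    stage = sample(paste0("II", c("", "I")), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  list(expr = expr_matrix(vals, platform), ann = ann)
}

#' Generate the protein-protein interaction network
#'
#' A simple undirected graph over all gene ids: background edges drawn
#' Bernoulli(`ppi_background_density`) over all pairs, plus every planted
#' motif forced in as a triangle. No self loops or duplicate edges.
#'
#' @param config a [synthetic_config()].
#' @return igraph object with all genes as nodes.
#' @export
generate_ppi <- function(config) {
  set.seed(config$seed + 500L)
  ids <- config$gene_ids
  n <- length(ids)
  # vectorized Bernoulli over the upper triangle
  npairs <- n * (n - 1) / 2
  hit <- which(stats::runif(npairs) < config$ppi_background_density)
  el <- if (length(hit)) {
    # map linear upper-triangle index (column-major, j > i) to (i, j)
    j <- ceiling((sqrt(8 * hit + 1) + 1) / 2)
    j <- j - (hit <= (j - 1) * (j - 2) / 2)        # float-boundary guard
    j <- j + (hit > j * (j - 1) / 2)
    i <- hit - (j - 1) * (j - 2) / 2
    cbind(ids[i], ids[j])
  } else matrix(character(0), 0L, 2L)
  planted <- do.call(rbind, lapply(seq_len(nrow(config$planted_motifs)),
                                   function(r) {
    tr <- config$planted_motifs[r, ]
    rbind(tr[c(1, 2)], tr[c(1, 3)], tr[c(2, 3)])
  }))
  g <- igraph::graph_from_edgelist(rbind(el, planted), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                            name = setdiff(ids, igraph::V(g)$name))
  igraph::simplify(g)
}

#' Attach proportional-hazards survival to a cohort
#'
#' Event times are Exponential with rate
#' `baseline_hazard * exp(sum(beta_g z_g) + age_beta z_age + sex_beta male)`
#' on row-standardized log-scale expression (counts are VST-transformed
#' first); censoring is an independent Exponential(`censor_rate`). Observed
#' time is the minimum, event the indicator of the event coming first.
#'
#' @param expr the cohort's [expr_matrix()].
#' @param ann the cohort's annotations.
#' @param config a [synthetic_config()].
#' @param cohort_index used to separate RNG streams across cohorts.
#' @return the annotations with `time` and `event` filled in.
#' @export
generate_survival <- function(expr, ann, config, cohort_index = 1L) {
  if (config$baseline_hazard <= 0) stop("baseline hazard must be positive")
  genes <- names(config$survival_betas)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("survival_betas reference unknown gene(s): ",
         paste(missing, collapse = ", "))
  logx <- if (platform_of(expr) == "counts") vst_transform(expr) else expr
  m <- as_plain_matrix(logx)
  lp <- rep(0, ncol(m))
  if (length(genes)) {
    z <- t(scale(t(m[genes, , drop = FALSE])))
    z[!is.finite(z)] <- 0
    lp <- lp + drop(crossprod(z, config$survival_betas[genes]))
  }
  lp <- lp + config$age_beta * as.numeric(scale(ann$age)) +
    config$sex_beta * as.numeric(ann$sex == "male")
  set.seed(config$seed + 7000L + cohort_index)
  t_event <- stats::rexp(ncol(m), rate = config$baseline_hazard * exp(lp))
  t_cens <- if (config$censor_rate > 0)
    stats::rexp(ncol(m), rate = config$censor_rate) else rep(Inf, ncol(m))
  ann$time <- pmin(t_event, t_cens)
  ann$event <- as.integer(t_event <= t_cens)
  ann
}

#' Generate the miRNA layer of a cohort
#'
#' Each miRNA's profile is `-strength * mean(standardized target
#' expression)` plus, for the planted discriminative pair, a per-class mean
#' shift in EMT samples, plus Gaussian noise. The accompanying target table
#' lists every (miRNA, gene) pair with `validated = TRUE`.
#'
#' @param expr the cohort's gene [expr_matrix()].
#' @param ann the cohort's annotations (for the subtype labels).
#' @param config a [synthetic_config()].
#' @param cohort_index RNG stream separator.
#' @return list: `mirna` ([expr_matrix()], platform `"intensity"`),
#'   `targets` (data frame `mirna`, `gene`, `validated`).
#' @export
generate_mirna_layer <- function(expr, ann, config, cohort_index = 1L) {
  tm <- config$mirna_target_map
  if (is.null(tm) || !nrow(tm)) {
    set.seed(config$seed + 9000L + cohort_index)
    vals <- matrix(stats::rnorm(config$n_mirnas * ncol(expr), 0,
                                config$mirna_noise_sd),
                   config$n_mirnas, ncol(expr),
                   dimnames = list(config$mirna_ids, colnames(expr)))
    return(list(mirna = expr_matrix(vals, "intensity"),
                targets = data.frame(mirna = character(0), gene = character(0),
                                     validated = logical(0))))
  }
  missing <- setdiff(tm$gene, rownames(expr))
  if (length(missing))
    stop("unknown target gene id(s): ", paste(missing, collapse = ", "))
  logx <- if (platform_of(expr) == "counts") vst_transform(expr) else expr
  z <- t(scale(t(as_plain_matrix(logx))))
  z[!is.finite(z)] <- 0
  is_emt <- ann$subtype == "EMT"
  set.seed(config$seed + 9000L + cohort_index)
  vals <- matrix(0, config$n_mirnas, ncol(expr),
                 dimnames = list(config$mirna_ids, colnames(expr)))
  for (k in seq_len(config$n_mirnas)) {
    mid <- config$mirna_ids[k]
    rows <- tm[tm$mirna == mid, , drop = FALSE]
    prof <- if (nrow(rows)) {
      -mean(rows$strength) * colMeans(z[rows$gene, , drop = FALSE])
    } else rep(0, ncol(expr))
    d <- match(mid, config$discriminative_mirnas)
    if (!is.na(d)) prof[is_emt] <- prof[is_emt] + config$discriminative_shifts[d]
    vals[k, ] <- prof
  }
  vals <- vals + matrix(stats::rnorm(length(vals), 0, config$mirna_noise_sd),
                        nrow(vals), ncol(vals))
  list(mirna = expr_matrix(vals, "intensity"),
       targets = data.frame(mirna = tm$mirna, gene = tm$gene,
                            validated = TRUE, stringsAsFactors = FALSE))
}

#' Generate the complete synthetic study
#'
#' All cohorts (expression + survival annotations + miRNA layer), the PPI
#' network, the target table, and the ground-truth labels.
#'
#' @param config a [synthetic_config()].
#' @return list of class `syn_study`: `cohorts` (each with `expr`, `ann`,
#'   `mirna`), `ppi`, `targets`, `truth`, `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  cohorts <- lapply(seq_along(config$cohort_sizes), function(i) {
    co <- generate_cohort(config, i)
    co$ann <- generate_survival(co$expr, co$ann, config, i)
    ml <- generate_mirna_layer(co$expr, co$ann, config, i)
    co$mirna <- ml$mirna
    co$targets <- ml$targets
    co
  })
  structure(list(cohorts = cohorts, ppi = generate_ppi(config),
                 targets = cohorts[[1L]]$targets,
                 truth = synthetic_truth(config), config = config),
            class = "syn_study")
}

#' @export
print.syn_study <- function(x, ...) {
  cat(sprintf("syn_study: %d cohorts, %d genes, %d miRNAs, %d PPI edges\n",
              length(x$cohorts), x$config$n_genes, x$config$n_mirnas,
              igraph::ecount(x$ppi)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Expression and miRNA matrices and annotations as TSV, the PPI network as
#' edge-list TSV and SIF, the target table as TSV, and the ground truth as
#' a plain-text key: value dump.
#'
#' @param study a `syn_study` from [generate_study()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(study$cohorts)) {
    co <- study$cohorts[[i]]
    write_expression(co$expr, file.path(outdir, sprintf("cohort%d_expr.tsv", i)))
    write_expression(co$mirna, file.path(outdir, sprintf("cohort%d_mirna.tsv", i)))
    write_annotations(co$ann, file.path(outdir, sprintf("cohort%d_ann.tsv", i)))
  }
  write_network(study$ppi, file.path(outdir, "ppi.tsv"))
  write_network(study$ppi, file.path(outdir, "ppi.sif"), format = "sif")
  write_target_table(study$targets, file.path(outdir, "targets.tsv"))
  tr <- study$truth
  lines <- c(
    paste0("seed: ", study$config$seed),
    paste0("emt_module_genes: ", paste(names(tr$de_genes), collapse = ",")),
    paste0("emt_effect_lfc: ", study$config$emt_effect_lfc),
    paste0("planted_motifs: ",
           paste(apply(tr$planted_motifs, 1L, paste, collapse = "|"),
                 collapse = ";")),
    paste0("survival_betas: ",
           paste(names(tr$survival_betas), tr$survival_betas, sep = "=",
                 collapse = ",")),
    paste0("discriminative_mirnas: ",
           paste(tr$discriminative_mirnas, collapse = ",")))
  writeLines(lines, file.path(outdir, "truth.txt"))
  invisible(outdir)
}
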