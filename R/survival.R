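#' Split samples into high/low expression groups
#'
#' High = the top `floor(fraction * n)` samples by expression, low = the
#' bottom `floor(fraction * n)`; middle samples are excluded. Boundary ties
#' are broken by stable sample order. With `fraction = 0.5` and even n the
#' two groups partition the samples.
#'
#' @param values named per-sample expression vector.
#' @param fraction quantile fraction in (0, 0.5]; default 0.4.
#' @return object of class `survival_groups`: list with `high`, `low`,
#'   `fraction`, `n_high`, `n_low`, `degenerate` (TRUE when all values tie).
#' @export
split_by_expression <- function(values, fraction = 0.4) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must lie in (0, 0.5]")
  n <- length(values)
  if (n < 5L) stop("need at least 5 samples")
  if (is.null(names(values))) stop("values must be named by sample id")
  k <- floor(fraction * n)
  ord <- order(-values)                 # stable: ties keep original order
  high <- names(values)[ord[seq_len(k)]]
  low <- names(values)[ord[seq(n - k + 1L, n)]]
  structure(list(high = high, low = low, fraction = fraction,
                 n_high = length(high), n_low = length(low),
                 degenerate = length(unique(values)) == 1L),
            class = "survival_groups")
}

#' @export
print.survival_groups <- function(x, ...) {
  cat(sprintf("survival_groups: %d high / %d low (fraction %.2f)%s\n",
              x$n_high, x$n_low, x$fraction,
              if (x$degenerate) " [degenerate: all values tied]" else ""))
  invisible(x)
}

#' High/low groups for a motif
#'
#' The motif's high-expression group is the intersection of the per-member
#' top-`fraction` sets; the low group is the intersection of the per-member
#' bottom sets. Samples with discordant member expression fall in neither.
#'
#' @param expr expression matrix (genes x samples).
#' @param motif character vector of three gene ids.
#' @param fraction per-gene quantile fraction (default 0.4).
#' @return a `survival_groups` object.
#' @export
motif_groups <- function(expr, motif, fraction = 0.4) {
  m <- as_plain_matrix(expr)
  missing <- setdiff(motif, rownames(m))
  if (length(missing))
    stop("motif gene(s) missing from expression: ", paste(missing, collapse = ", "))
  splits <- lapply(motif, function(g) split_by_expression(m[g, ], fraction))
  high <- Reduce(intersect, lapply(splits, `[[`, "high"))
  low <- Reduce(intersect, lapply(splits, `[[`, "low"))
  structure(list(high = high, low = low, fraction = fraction,
                 n_high = length(high), n_low = length(low),
                 degenerate = any(vapply(splits, `[[`, logical(1), "degenerate"))),
            class = "survival_groups")
}

#' Motif sample-size filter
#'
#' A motif's grouping is analyzable when each of the high and low groups
#' has at least `min_per_group` samples and together they contain at least
#' `min_total` samples.
#'
#' @param groups a `survival_groups` object.
#' @param min_per_group per-group minimum (default 30).
#' @param min_total combined minimum (default 100).
#' @return logical.
#' @export
filter_motif_groups <- function(groups, min_per_group = 30L, min_total = 100L) {
  groups$n_high >= min_per_group && groups$n_low >= min_per_group &&
    (groups$n_high + groups$n_low) >= min_total
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival curve with right censoring, plus the median
#' survival time (NA when the curve never reaches 0.5).
#'
#' @param time follow-up times (>= 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @return list of class `km_estimate`: `time`, `surv` (step function
#'   coordinates; S(0) = 1 implied), `n_risk`, `n_event`, `median`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("empty input")
  if (any(time < 0)) stop("times must be nonnegative")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("km_estimate: %d time points, median survival %s\n",
              length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Evaluate a KM curve at arbitrary times
#' @param km a `km_estimate`.
#' @param t times to evaluate at.
#' @return S(t), right-continuous step function with S(0) = 1.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' @param time_a,event_a follow-up and event indicator for group A.
#' @param time_b,event_b same for group B.
#' @return list with `chisq` and `pvalue`; with no events at all the test
#'   is undefined and (0, 1) is returned.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0) return(list(chisq = 0, pvalue = 1))
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chisq = unname(sd$chisq),
       pvalue = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Covariate-adjusted Cox model for an expression-defined group
#'
#' Cox proportional-hazards partial likelihood with Breslow tie handling,
#' fitting the high/low group indicator with age (z-scored) and sex (0/1)
#' as confounder covariates. Reports the hazard ratio of the group term
#' (high vs low), its Wald p-value, and the covariate coefficients.
#'
#' @param time,event follow-up and event indicator.
#' @param group 0/1 (or logical) indicator, 1 = high expression.
#' @param age optional numeric age; standardized internally.
#' @param sex optional 0/1 (or "male"/"female") covariate.
#' @return object of class `cox_result`: `hr`, `beta`, `se`, `pvalue`,
#'   `covariates` (named betas), `n_used`, `converged`, `monotone`
#'   (TRUE when the likelihood is monotone / coefficient diverges).
#' @export
cox_fit <- function(time, event, group, age = NULL, sex = NULL) {
  if (sum(event) < 1L) stop("need at least one event")
  df <- data.frame(time = time, event = event, group = as.numeric(group))
  form <- "survival::Surv(time, event) ~ group"
  if (!is.null(age)) {
    df$age <- as.numeric(scale(as.numeric(age)))
    form <- paste(form, "+ age")
  }
  if (!is.null(sex)) {
    df$sex <- if (is.character(sex) || is.factor(sex))
      as.numeric(sex == "male") else as.numeric(sex)
    form <- paste(form, "+ sex")
  }
  fit <- survival::coxph(stats::as.formula(form), data = df, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50L))
  beta <- unname(stats::coef(fit)["group"])
  se <- sqrt(diag(fit$var))[1L]
  monotone <- !is.finite(beta) || abs(beta) > 15 || se > 100
  covars <- stats::coef(fit)[setdiff(names(stats::coef(fit)), "group")]
  structure(list(hr = exp(beta), beta = beta, se = se,
                 pvalue = 2 * stats::pnorm(-abs(beta / se)),
                 covariates = covars, n_used = fit$n,
                 converged = is.null(fit$fail), monotone = monotone),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("cox_result: HR = %.3f (beta %.3f +/- %.3f), p = %.3g, n = %d%s\n",
              x$hr, x$beta, x$se, x$pvalue, x$n_used,
              if (x$monotone) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Motif survival screen
#'
#' For every motif: build the intersection-based high/low groups, apply the
#' sample-size filter, and fit the covariate-adjusted Cox model on the
#' passing motifs.
#'
#' @param expr expression matrix (genes x samples), normalized scale.
#' @param ann annotation data frame (sample_id, age, sex, time, event).
#' @param motifs character matrix (rows = motifs, 3 columns).
#' @param fraction quantile fraction (default 0.4).
#' @param min_per_group,min_total filter thresholds (defaults 30, 100).
#' @return data frame: motif, n_high, n_low, pass_filter, hr, beta, pvalue.
#' @export
motif_survival <- function(expr, ann, motifs, fraction = 0.4,
                           min_per_group = 30L, min_total = 100L) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(ann)))
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    motif <- as.character(motifs[i, 1:3])
    gr <- motif_groups(expr, motif, fraction)
    pass <- filter_motif_groups(gr, min_per_group, min_total)
    hr <- beta <- p <- NA_real_
    if (pass) {
      ids <- c(gr$high, gr$low)
      idx <- match(ids, ann$sample_id)
      cf <- tryCatch(
        cox_fit(ann$time[idx], ann$event[idx],
                as.numeric(ids %in% gr$high), ann$age[idx], ann$sex[idx]),
        error = function(e) NULL)
      if (!is.null(cf)) { hr <- cf$hr; beta <- cf$beta; p <- cf$pvalue }
    }
    data.frame(motif = paste(motif, collapse = "|"),
               n_high = gr$n_high, n_low = gr$n_low, pass_filter = pass,
               hr = hr, beta = beta, pvalue = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-cohort consistent top motifs
#'
#' Restricts each cohort's motif survival results to motifs passing the
#' sample-size filter in both cohorts, ranks each cohort's motifs by hazard
#' ratio (descending; ties broken by smaller Cox p), and returns the
#' intersection of the two top-k lists.
#'
#' @param results_a,results_b data frames from [motif_survival()].
#' @param k list depth (default 5).
#' @return character vector of motif keys ("g1|g2|g3").
#' @export
consistent_top_motifs <- function(results_a, results_b, k = 5L) {
  both <- intersect(results_a$motif[results_a$pass_filter],
                    results_b$motif[results_b$pass_filter])
  top <- function(res) {
    res <- res[res$motif %in% both & is.finite(res$hr), ]
    res <- res[order(-res$hr, res$pvalue), ]
    utils::head(res$motif, k)
  }
  intersect(top(results_a), top(results_b))
}
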