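test_that("expression split takes the stated quantile groups", {
  v <- stats::setNames(1:10, paste0("s", 1:10))
  gr <- split_by_expression(v, 0.4)
  expect_setequal(gr$high, paste0("s", 7:10))
  expect_setequal(gr$low, paste0("s", 1:4))
  expect_equal(c(gr$n_high, gr$n_low), c(4L, 4L))

  # all-equal values: stable order fills the groups, flagged degenerate
  tied <- stats::setNames(rep(5, 10), paste0("s", 1:10))
  gt <- split_by_expression(tied, 0.4)
  expect_true(gt$degenerate)
  expect_equal(gt$n_high + gt$n_low, 8L)
  expect_length(intersect(gt$high, gt$low), 0L)

  # fraction 0.5 with even n partitions the samples
  gp <- split_by_expression(v, 0.5)
  expect_setequal(c(gp$high, gp$low), names(v))
  expect_error(split_by_expression(v[1:4]), "5 samples")
  expect_error(split_by_expression(v, 0.6), "fraction")
  # group sizes always floor(fraction * n)
  for (n in c(7, 11, 23)) {
    g <- split_by_expression(stats::setNames(rnorm(n), paste0("x", 1:n)), 0.4)
    expect_equal(g$n_high, floor(0.4 * n))
    expect_equal(g$n_low, floor(0.4 * n))
  }
})

test_that("motif groups are the intersections of member splits", {
  prof <- stats::setNames(rnorm(50), paste0("s", 1:50))
  m <- rbind(g1 = prof, g2 = prof, g3 = prof)
  gr <- motif_groups(m, c("g1", "g2", "g3"), 0.4)
  single <- split_by_expression(prof, 0.4)
  expect_setequal(gr$high, single$high)
  expect_setequal(gr$low, single$low)

  set.seed(26)
  ind <- matrix(rnorm(3 * 300), 3, 300,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:300)))
  gi <- motif_groups(ind, paste0("g", 1:3), 0.4)
  expected <- 300 * 0.4^3
  sd3 <- sqrt(300 * 0.4^3 * (1 - 0.4^3))
  expect_lt(abs(gi$n_high - expected), 3 * sd3 + 1)

  anti <- rbind(g1 = prof, g2 = -prof, g3 = prof)
  ga <- motif_groups(anti, paste0("g", 1:3), 0.4)
  expect_equal(ga$n_high + ga$n_low, 0L)
  expect_error(motif_groups(m, c("g1", "g2", "zz")), "zz")
})

test_that("the sample-size filter reproduces its thresholds exactly", {
  mk <- function(h, l) structure(list(high = paste0("h", seq_len(h)),
                                      low = paste0("l", seq_len(l)),
                                      n_high = h, n_low = l,
                                      fraction = 0.4, degenerate = FALSE),
                                 class = "survival_groups")
  expect_false(filter_motif_groups(mk(35, 40)))   # total 75 < 100
  expect_true(filter_motif_groups(mk(60, 50)))
  expect_false(filter_motif_groups(mk(29, 200)))  # per-group bound
  expect_true(filter_motif_groups(mk(50, 50)))    # boundary: exactly 100
  expect_true(filter_motif_groups(mk(30, 70)))
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  km <- km_estimate(c(2, 3, 5), c(1, 0, 1))
  expect_equal(km_survival_at(km, 2), 2 / 3)
  expect_equal(km_survival_at(km, 5), 0)
  expect_equal(km_survival_at(km, 0), 1)

  none <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(none$surv == 1))

  # without censoring the KM curve is the empirical survivor function
  set.seed(27)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  grid <- seq(0, 3, by = 0.1)
  expect_equal(km_survival_at(km2, grid),
               vapply(grid, function(g) mean(t > g), numeric(1)))
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test is calibrated and matches a hand risk table", {
  same <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(same$chisq, 0, tolerance = 1e-10)
  expect_equal(same$pvalue, 1, tolerance = 1e-10)
  expect_equal(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))$pvalue, 1)

  # hand computation on 6 samples, no ties across groups:
  # A: events at 1, 3; B: events at 2, 4; censored A 5+, B 6+
  hand <- logrank_test(c(1, 3, 5), c(1, 1, 0), c(2, 4, 6), c(1, 1, 0))
  # risk sets: t=1 (3A,3B) E_A=1/2; t=2 (2A,3B) e_A=0, E=2/5; t=3 (2A,2B)
  # E=1/2; t=4 (1A,2B) e_A=0, E=1/3. O_A=2, E_A=0.5+0.4+0.5+1/3
  ea <- 0.5 + 0.4 + 0.5 + 1 / 3
  va <- (0.5 * 0.5) + (0.4 * 0.6) + (0.5 * 0.5) + (1 / 3 * 2 / 3)
  expect_equal(hand$chisq, (2 - ea)^2 / va, tolerance = 1e-6)

  # power at a generated hazard ratio of 3
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    ta <- rexp(100, 0.03); tb <- rexp(100, 0.01)
    logrank_test(ta, rep(1, 100), tb, rep(1, 100))$pvalue < 0.01
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("Cox fits recover generating coefficients", {
  set.seed(28)
  n <- 500
  grp <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 62, 11)
  sex <- rbinom(n, 1, 0.6)
  lp0 <- 0 * grp + 0.3 * scale(age)[, 1] + 0.3 * sex
  t0 <- rexp(n, 0.02 * exp(lp0))
  null_fit <- cox_fit(t0, rep(1, n), grp, age, sex)
  expect_lt(abs(null_fit$beta), 0.15)

  lp3 <- log(3) * grp + 0.3 * scale(age)[, 1] + 0.3 * sex
  t3 <- rexp(n, 0.02 * exp(lp3))
  fit3 <- cox_fit(t3, rep(1, n), grp, age, sex)
  expect_gte(fit3$hr, 2.4)
  expect_lte(fit3$hr, 3.75)
  expect_equal(fit3$hr, exp(fit3$beta))
  expect_named(fit3$covariates, c("age", "sex"))
  expect_error(cox_fit(t3, rep(0, n), grp), "event")
})

test_that("Cox beta matches a brute-force Breslow grid on 8 observations", {
  time <- c(1, 2, 2, 3, 5, 6, 8, 9)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0, 1, 0)
  fit <- cox_fit(time, event, x)
  breslow_loglik <- function(b) {
    ll <- 0
    for (tt in unique(time[event == 1])) {
      d <- which(time == tt & event == 1)
      risk <- which(time >= tt)
      ll <- ll + b * sum(x[d]) - length(d) * log(sum(exp(b * x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  best <- grid[which.max(vapply(grid, breslow_loglik, numeric(1)))]
  expect_equal(fit$beta, best, tolerance = 1e-3)
})

test_that("the cross-cohort consistency rule intersects top-HR lists", {
  mk <- function(motifs, hrs, ps = rep(0.01, length(hrs)),
                 pass = rep(TRUE, length(hrs))) {
    data.frame(motif = motifs, n_high = 40, n_low = 40, pass_filter = pass,
               hr = hrs, beta = log(hrs), pvalue = ps,
               stringsAsFactors = FALSE)
  }
  a <- mk(paste0("m", 1:8), 8:1)
  expect_equal(consistent_top_motifs(a, a, k = 5), paste0("m", 1:5))
  b <- mk(paste0("m", 1:8), 1:8)
  expect_length(consistent_top_motifs(a, b, k = 3), 0L)
  # a motif failing the filter in one cohort is excluded everywhere
  c2 <- mk(paste0("m", 1:8), 8:1, pass = c(FALSE, rep(TRUE, 7)))
  expect_false("m1" %in% consistent_top_motifs(a, c2, k = 5))
})

test_that("a planted high-hazard motif survives the cross-cohort screen", {
  hits <- vapply(1:20, function(s) {
    cfg <- synthetic_config(
      n_genes = 400L, n_mirnas = 0L, cohort_sizes = c(300L, 300L),
      platforms = c("counts", "intensity"),
      module_plan = data.frame(size = 60L, loading_mean = 0.6,
                               loading_sd = 0.1),
      survival_betas = stats::setNames(rep(0.5, 3), c("g0001", "g0002", "g0003")),
      seed = s)
    decoys <- rbind(c("g0013", "g0014", "g0015"), c("g0023", "g0024", "g0025"),
                    c("g0033", "g0034", "g0035"), c("g0101", "g0102", "g0103"),
                    c("g0201", "g0202", "g0203"))
    motifs <- rbind(cfg$planted_motifs[1, , drop = FALSE], decoys)
    res <- lapply(1:2, function(i) {
      co <- generate_cohort(cfg, i)
      ann <- generate_survival(co$expr, co$ann, cfg, i)
      norm <- if (platform_of(co$expr) == "counts") vst_transform(co$expr)
              else co$expr
      motif_survival(norm, ann, motifs)
    })
    key <- paste(cfg$planted_motifs[1, ], collapse = "|")
    key %in% consistent_top_motifs(res[[1]], res[[2]], k = 5)
  }, logical(1))
  expect_gte(sum(hits), 18L)
})
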