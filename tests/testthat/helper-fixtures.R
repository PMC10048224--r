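# small synthetic configurations used across test files

small_config <- function(seed = 1L, ...) {
  synthetic_config(
    n_genes = 300L, n_mirnas = 30L,
    cohort_sizes = c(80L, 80L),
    platforms = c("counts", "intensity"),
    module_plan = data.frame(size = c(40L, 30L), loading_mean = 0.6,
                             loading_sd = 0.1),
    seed = seed, ...)
}

# factor-model expression block: `size` genes driven by one latent factor
# with within-block correlation ~ loading^2 / (loading^2 + noise^2)
block_expr <- function(size, n_samples, loading = 2, noise = 1, seed = 1L,
                       prefix = "b") {
  set.seed(seed)
  f <- rnorm(n_samples)
  m <- matrix(loading * rep(f, each = size) +
                rnorm(size * n_samples, 0, noise), size, n_samples)
  rownames(m) <- sprintf("%s%03d", prefix, seq_len(size))
  colnames(m) <- sprintf("s%03d", seq_len(n_samples))
  m
}

rand_counts <- function(nr = 6, nc = 4, seed = 1L, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, lambda), nr, nc,
              dimnames = list(sprintf("g%02d", 1:nr), sprintf("s%02d", 1:nc)))
  expr_matrix(m, "counts")
}

triple_keys <- function(mat) {
  apply(mat, 1L, function(r) paste(sort(r), collapse = "|"))
}
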