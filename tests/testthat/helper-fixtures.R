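# Shared fixtures and independent oracles, built in code at test time.

# Tiny expression matrix with deterministic values.
tiny_expr <- function(genes = 3L, samples = 4L, prefix = "g", seed = 1L,
                      gene_class = "mrna") {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples), nrow = genes,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  expression_matrix(m, gene_class)
}

write_expr_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent hypergeometric oracle: direct factorial enumeration of
# P(X >= L) for X ~ Hypergeometric(N, M, K). Returns the whole tail vector
# over L = 0..min(M,K) via a reverse cumulative sum of exact cell masses.
hyper_tail_oracle <- function(N, M, K) {
  lo <- max(0L, M + K - N)
  hi <- min(M, K)
  xs <- lo:hi
  mass <- vapply(xs, function(x)
    exp(lfactorial(M) - lfactorial(x) - lfactorial(M - x) +
        lfactorial(N - M) - lfactorial(K - x) - lfactorial(N - M - (K - x)) +
        lfactorial(K) + lfactorial(N - K) - lfactorial(N)), numeric(1L))
  # tail[l + 1] = P(X >= l) for l in 0..hi
  tails <- rev(cumsum(rev(mass)))
  c(rep(1, lo), tails)
}

# Student-t density integrated numerically (independent of pt()).
t_density <- function(t, v) {
  exp(lgamma((v + 1) / 2) - lgamma(v / 2)) / sqrt(v * pi) *
    (1 + t^2 / v)^(-(v + 1) / 2)
}

t_upper_tail_numint <- function(tval, v) {
  integrate(t_density, lower = abs(tval), upper = Inf, v = v,
            rel.tol = 1e-13, abs.tol = 1e-14)$value
}

# Write a simulated dataset to disk in the pipeline's input layout.
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(expression = list(), targets = list())
  for (cl in names(sim$dataset))
    paths$expression[[cl]] <-
      write_expr_tsv(sim$dataset[[cl]], file.path(dir, paste0(cl, ".tsv")))
  for (cl in names(sim$priors)) {
    p <- file.path(dir, paste0("targets_", cl, ".tsv"))
    write.table(sim$priors[[cl]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$targets[[cl]] <- p
  }
  paths
}

# A small planted dataset + null model shared across test files (built once).
small_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_dataset(sim_config(seed = 42))
    val
  }
})

small_null_model <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- build_null_model(200, m_bins = c(1, 2, 3, 5, 10),
                               cor_bins = seq(0.05, 0.95, by = 0.1),
                               draws_per_cell = 300, seed = 9)
    val
  }
})
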