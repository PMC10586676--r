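#' Empirical null model for the sensitive correlation
#'
#' Simulates the sampling distribution of the sensitive correlation under the
#' null hypothesis that the conditioning set does not affect the correlation
#' of the tested pair (population `sc = 0`). For each cell of a grid over
#' conditioning-set size `m` and pair correlation `c`, data are drawn from an
#' `(m + 2)`-dimensional normal with unit variances, `cov(x, y) = c`, and all
#' conditioning variables independent of the pair and of each other — the
#' simplest covariance family whose population sensitive correlation is
#' exactly zero. Each cell stores `draws_per_cell` sample sensitive
#' correlations computed from datasets of `sample_size` observations.
#'
#' @param sample_size number of samples `s` of the data the model will be
#'   used on (`>= 5`).
#' @param m_bins conditioning-set sizes to simulate (default `1:10`; observed
#'   sizes above the maximum are mapped to the largest bin at lookup).
#' @param cor_bins correlation-bin centers (default `0.05, 0.15, ..., 0.95`,
#'   width 0.1); all must lie in `(-1, 1)`.
#' @param draws_per_cell simulated datasets per cell (default 1000).
#' @param seed integer seed; the model is reproducible given the seed.
#' @return object of class `"scom_null_model"`.
#' @export
build_null_model <- function(sample_size, m_bins = 1:10,
                             cor_bins = seq(0.05, 0.95, by = 0.1),
                             draws_per_cell = 1000L, seed = 1L) {
  if (sample_size < 5L) stop("'sample_size' must be >= 5", call. = FALSE)
  if (!length(m_bins) || !length(cor_bins))
    stop("'m_bins' and 'cor_bins' must be non-empty", call. = FALSE)
  if (any(m_bins < 1L) || any(m_bins != round(m_bins)))
    stop("'m_bins' must be positive integers", call. = FALSE)
  if (any(abs(cor_bins) >= 1))
    stop("'cor_bins' must lie strictly inside (-1, 1)", call. = FALSE)
  m_bins <- sort(as.integer(m_bins))
  cor_bins <- sort(cor_bins)
  s <- as.integer(sample_size)
  D <- as.integer(draws_per_cell)

  null_sc <- with_seed(seed, {
    arr <- array(NA_real_,
                 dim = c(D, length(m_bins), length(cor_bins)),
                 dimnames = list(NULL, paste0("m", m_bins),
                                 paste0("c", cor_bins)))
    for (mi in seq_along(m_bins)) {
      m <- m_bins[mi]
      for (ci in seq_along(cor_bins)) {
        cc <- cor_bins[ci]
        for (d in seq_len(D)) {
          x <- rnorm(s)
          y <- cc * x + sqrt(1 - cc^2) * rnorm(s)
          z <- matrix(rnorm(s * m), nrow = s)
          arr[d, mi, ci] <- sample_sc(x, y, z)
        }
      }
    }
    arr
  })
  structure(list(sample_size = s, m_bins = m_bins, cor_bins = cor_bins,
                 draws_per_cell = D, seed = as.integer(seed),
                 null_sc = null_sc),
            class = "scom_null_model")
}

# Sample sensitive correlation of one simulated dataset; fast path used only
# inside the null model (inputs are continuous random draws, never collinear).
sample_sc <- function(x, y, z) {
  R <- cor(cbind(x, y, z))
  P <- solve(R)
  R[1L, 2L] + P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

#' @export
print.scom_null_model <- function(x, ...) {
  cat("Zero-sensitivity null model: s =", x$sample_size,
      "|", length(x$m_bins), "conditioning bins x", length(x$cor_bins),
      "correlation bins x", x$draws_per_cell, "draws (seed", x$seed, ")\n")
  invisible(x)
}

#' Empirical p-value of an observed sensitive correlation
#'
#' Looks up the null-model cell nearest to the observed conditioning-set size
#' (capped at the largest simulated size) and correlation, and returns the
#' one-sided, add-one-smoothed right-tail p-value
#' `(1 + #\{null sc >= observed\}) / (1 + draws)`: large positive sensitive
#' correlation is the competition signal.
#'
#' @param sc_observed observed sensitive correlation; `NA` (degenerate)
#'   propagates to an `NA` p-value.
#' @param conditioning_size number of conditioning variables used (`>= 1`).
#' @param cor observed pair correlation (bin selector).
#' @param model a [build_null_model()] object.
#' @return p-value in `[1/(draws+1), 1]`, or `NA`.
#' @export
null_pvalue <- function(sc_observed, conditioning_size, cor, model) {
  stopifnot(inherits(model, "scom_null_model"))
  if (is.na(sc_observed)) return(NA_real_)
  if (conditioning_size < 1L)
    stop("'conditioning_size' must be >= 1", call. = FALSE)
  m <- min(conditioning_size, max(model$m_bins))
  mi <- which.min(abs(model$m_bins - m))
  ci <- which.min(abs(model$cor_bins - cor))
  draws <- model$null_sc[, mi, ci]
  (1 + sum(draws >= sc_observed)) / (1 + model$draws_per_cell)
}
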